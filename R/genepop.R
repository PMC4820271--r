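#' Read a Genepop file
#'
#' Parses the standard Genepop text format: a title line, one locus name per
#' line (or a single comma-separated line), then `POP` blocks, each holding
#' records `id , g1 g2 g3 g4` where every genotype is a concatenation of two
#' fixed-width allele codes (2- or 3-digit coding; `"00"`/`"000"` is a
#' missing allele). Each `POP` block becomes one sample.
#'
#' @param path path to a `.gen` file.
#' @param sample_ids optional character vector naming the POP blocks; default
#'   `pop1`, `pop2`, ...
#' @return a [genotype_table()]; allele codes are preserved verbatim as
#'   labels, genotypes with a missing coded allele become missing cells.
#' @export
read_genepop <- function(path, sample_ids = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3L) stop("Genepop parse error: file too short")
  is_pop <- toupper(trimws(lines)) %in% c("POP")
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop) || first_pop < 3L)
    stop("Genepop parse error: no POP line after the locus list (line ",
         ifelse(is.na(first_pop), "none", first_pop), ")")
  locus_lines <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("Genepop parse error: empty locus list")
  pop_starts <- which(is_pop)
  ids <- a1l <- a2l <- samp <- list()
  pop_i <- 0L
  for (k in seq_along(pop_starts)) {
    pop_i <- pop_i + 1L
    from <- pop_starts[k] + 1L
    to <- if (k < length(pop_starts)) pop_starts[k + 1L] - 1L else length(lines)
    if (to < from) next
    block <- lines[from:to]
    block <- block[nzchar(trimws(block))]
    for (ln in block) {
      parts <- strsplit(ln, ",")[[1L]]
      if (length(parts) < 2L)
        stop("Genepop parse error: record without comma: '", ln, "'")
      id <- trimws(parts[1L])
      codes <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
      if (length(codes) != length(loci))
        stop("Genepop parse error: individual '", id, "' has ",
             length(codes), " genotypes for ", length(loci), " loci")
      w <- unique(nchar(codes))
      if (length(w) != 1L || !(w %in% c(4L, 6L)))
        stop("Genepop format error: allele strings for '", id,
             "' are not uniformly 4 or 6 characters")
      half <- w %/% 2L
      x1 <- substr(codes, 1L, half)
      x2 <- substr(codes, half + 1L, w)
      miss <- x1 == strrep("0", half) | x2 == strrep("0", half)
      x1[miss] <- NA_character_; x2[miss] <- NA_character_
      ids[[length(ids) + 1L]] <- id
      a1l[[length(a1l) + 1L]] <- x1
      a2l[[length(a2l) + 1L]] <- x2
      samp[[length(samp) + 1L]] <- pop_i
    }
  }
  if (length(ids) == 0L) stop("Genepop parse error: no individuals")
  pop_idx <- unlist(samp)
  if (is.null(sample_ids)) sample_ids <- paste0("pop", seq_len(max(pop_idx)))
  ids <- unlist(ids)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  genotype_table(ids, loci,
                 do.call(rbind, a1l), do.call(rbind, a2l),
                 sample_id = sample_ids[pop_idx])
}

#' Write a Genepop file
#'
#' Inverse of [read_genepop()]: individuals are grouped into `POP` blocks by
#' `sample_id` (in order of first appearance). Allele labels must be numeric
#' codes of width at most 3; they are zero-padded to a uniform 2- or 3-digit
#' coding. Missing genotypes are written as all-zero codes.
#'
#' @param table a [genotype_table()].
#' @param path output path.
#' @param title title line written as the first line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path, title = "musselmix genotypes") {
  labs <- c(table$a1, table$a2)
  labs <- labs[!is.na(labs)]
  if (length(labs) && any(!grepl("^[0-9]+$", labs)))
    stop("Genepop output needs numeric allele codes")
  width <- if (length(labs) && max(nchar(labs)) > 2L) 3L else 2L
  pad <- function(m) {
    out <- ifelse(is.na(m), strrep("0", width),
                  formatC(m, width = width, flag = "0"))
    matrix(out, nrow = nrow(m))
  }
  p1 <- pad(table$a1); p2 <- pad(table$a2)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(title, table$loci), con)
  for (s in unique(table$sample_id)) {
    writeLines("POP", con)
    idx <- which(table$sample_id == s)
    for (i in idx) {
      g <- paste0(p1[i, ], p2[i, ], collapse = " ")
      writeLines(paste0(table$individuals[i], " , ", g), con)
    }
  }
  invisible(path)
}

#' Read a tabular genotype file
#'
#' Reads the package's flat dialect: a TSV with columns `id`, `sample`,
#' `site`, `substrate`, then one column per locus holding `a1/a2` allele
#' pairs (empty or `NA` for missing).
#'
#' @param path path to a TSV file.
#' @return a [genotype_table()].
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  meta <- c("id", "sample", "site", "substrate")
  if (!all(meta %in% names(df)))
    stop("tabular genotype file must have columns ", paste(meta, collapse = ", "))
  loci <- setdiff(names(df), meta)
  split2 <- function(v) {
    v[v %in% c("", "NA")] <- NA_character_
    parts <- strsplit(v, "/", fixed = TRUE)
    bad <- !is.na(v) & lengths(parts) != 2L
    if (any(bad)) stop("malformed genotype pair: '", v[which(bad)[1L]], "'")
    cbind(vapply(parts, function(p) if (length(p) == 2L) p[1L] else NA_character_, ""),
          vapply(parts, function(p) if (length(p) == 2L) p[2L] else NA_character_, ""))
  }
  pairs <- lapply(loci, function(l) split2(df[[l]]))
  genotype_table(df$id, loci,
                 do.call(cbind, lapply(pairs, function(p) p[, 1L])),
                 do.call(cbind, lapply(pairs, function(p) p[, 2L])),
                 sample_id = df$sample, site_id = df$site,
                 substrate = df$substrate)
}

#' Write a tabular genotype file
#'
#' @param table a [genotype_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(table, path) {
  gcols <- lapply(seq_along(table$loci), function(j) {
    v <- paste0(table$a1[, j], "/", table$a2[, j])
    v[is.na(table$a1[, j])] <- NA_character_
    v
  })
  names(gcols) <- table$loci
  df <- data.frame(id = table$individuals, sample = table$sample_id,
                   site = table$site_id, substrate = table$substrate,
                   gcols, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
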