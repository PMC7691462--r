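#' Write a labelled site-by-site matrix as CSV
#'
#' First row and first column carry the site ids.
#' @param m square matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(!is.null(rownames(m)))
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Read a labelled site-by-site matrix from CSV
#' @param path CSV written by [write_matrix_csv].
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write genotypes as a minimal plain-text VCF
#'
#' Emits a VCFv4.2 file with `GT`-only genotype fields (0/0, 0/1, 1/1, ./.),
#' one record per SNP; the locus group (when present) is stored in the ID
#' column. Sample ids are the individual ids.
#'
#' @param gt a [genotypes] object.
#' @param path output file (uncompressed `.vcf`).
#' @export
write_vcf <- function(gt, path) {
  stopifnot(inherits(gt, "genotypes"))
  G <- gt$G
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=riverscape",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(G)),
                     collapse = "\t")), con)
  ids <- if (!is.null(gt$locus_groups)) gt$locus_groups else colnames(G)
  for (l in seq_len(ncol(G))) {
    gts <- ifelse(is.na(G[, l]), "./.", code[as.character(G[, l])])
    writeLines(paste(c("1", l, ids[l], "A", "T", ".", "PASS", ".", "GT",
                       gts), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Reads the `GT` field of a (biallelic SNP) VCF via `vcfR` and converts it
#' to the 0/1/2 alternate-allele-count encoding. Population labels come from
#' `popmap` (data.frame `individual, site_id`) or, when omitted, from the
#' text before the last underscore of each sample id.
#'
#' @param path VCF file.
#' @param popmap optional data.frame mapping individuals to sites.
#' @return a [genotypes] object.
#' @export
read_vcf_genotypes <- function(path, popmap = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path),
                               call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gtc <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(s) {
    ifelse(is.na(s) | s %in% c("./.", ".|."), NA_integer_,
           (substr(s, 1, 1) == "1") + (substr(s, 3, 3) == "1"))
  }
  G <- t(apply(gtc, 2, count_alt))
  colnames(G) <- rownames(gtc)
  inds <- rownames(G)
  if (is.null(popmap)) {
    pops <- sub("_[^_]*$", "", inds)
  } else {
    pops <- popmap$site_id[match(inds, popmap$individual)]
    if (anyNA(pops)) stop("popmap does not cover all individuals",
                          call. = FALSE)
  }
  ids <- vcfR::getID(v)
  genotypes(G, pops, locus_groups = if (anyNA(ids)) NULL else ids)
}

#' Write genotypes in genepop format
#'
#' Two-digit allele coding (01 = reference, 02 = alternate, 0000 = missing),
#' one locus name per line, sites separated by `Pop` lines.
#'
#' @param gt a [genotypes] object.
#' @param path output file.
#' @param title first (comment) line.
#' @export
write_genepop <- function(gt, path, title = "riverscape export") {
  stopifnot(inherits(gt, "genotypes"))
  G <- gt$G
  code <- c(`0` = "0101", `1` = "0102", `2` = "0202")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(colnames(G), con)
  for (s in sort(unique(gt$pops))) {
    writeLines("Pop", con)
    for (i in which(gt$pops == s)) {
      al <- ifelse(is.na(G[i, ]), "0000", code[as.character(G[i, ])])
      writeLines(paste0(rownames(G)[i], " ,  ", paste(al, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Read a genepop file
#'
#' Supports the common layout: title line, locus names (one per line or
#' comma-separated on one line), `Pop` separators, and per-individual lines
#' `id , 0101 0102 ...` with 2- or 3-digit allele codes. The individual id
#' doubles as the sample name; each `Pop` block becomes one site, labelled
#' by its first individual's id prefix (text before the last underscore) or
#' `pop<k>` when ids carry no prefix.
#'
#' @param path genepop file.
#' @return a [genotypes] object.
#' @export
read_genepop <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  body_start <- which(toupper(lines) == "POP")[1]
  if (is.na(body_start)) stop("no 'Pop' line found", call. = FALSE)
  loci <- lines[2:(body_start - 1)]
  if (length(loci) == 1 && grepl(",", loci))
    loci <- trimws(strsplit(loci, ",")[[1]])
  rows <- list(); pops <- character(0); inds <- character(0)
  pop_idx <- 0L
  for (ln in lines[body_start:length(lines)]) {
    if (toupper(ln) == "POP") { pop_idx <- pop_idx + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    id <- trimws(parts[1])
    al <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    w <- nchar(al[1]) / 2
    a1 <- as.integer(substr(al, 1, w))
    a2 <- as.integer(substr(al, w + 1, 2 * w))
    gcode <- ifelse(a1 == 0 | a2 == 0, NA_integer_,
                    (a1 == 2L) + (a2 == 2L))
    rows[[length(rows) + 1L]] <- gcode
    inds <- c(inds, id)
    pops <- c(pops, as.character(pop_idx))
  }
  G <- do.call(rbind, rows)
  rownames(G) <- inds
  colnames(G) <- loci
  ## prefer the id prefix as the site label when consistent within blocks
  pref <- sub("_[^_]*$", "", inds)
  by_block <- split(pref, pops)
  labels <- vapply(names(by_block), function(b) {
    u <- unique(by_block[[b]])
    if (length(u) == 1 && nzchar(u) && u != inds[pops == b][1])
      u else paste0("pop", b)
  }, character(1))
  genotypes(G, unname(labels[pops]))
}

#' Write the per-site diversity table
#'
#' Site, sample size, expected heterozygosity and population-specific FST,
#' the conventional per-site summary table.
#'
#' @param gt a [genotypes] object.
#' @param path output CSV.
#' @return the table, invisibly written to `path`.
#' @export
write_diversity_table <- function(gt, path = NULL) {
  he <- expected_heterozygosity(gt)
  beta <- popspecific_fst_wh(gt)
  tab <- data.frame(site = names(he),
                    N = as.vector(table(gt$pops)[names(he)]),
                    H_E = round(he, 4),
                    F_ST = round(beta[names(he)], 4))
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
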