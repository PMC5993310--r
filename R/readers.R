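#' Read a Genepop file
#'
#' Parses the classic Genepop text format (title line, locus names, `POP`
#' blocks, fixed-width 2- or 3-digit allele codes, diploid). Allele code
#' `00`/`000` marks a missing allele; a genotype containing any missing
#' allele code is treated as a missing genotype. `POP` block membership is
#' attached as the `"pop"` attribute of the result (prior labels only; the
#' clustering itself never uses them).
#'
#' @param path path to a Genepop (.gen) file.
#' @return A [genotype_matrix] (ploidy 2) with attribute `pop`, a factor of
#'   POP-block labels.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 4L) stop("Genepop file too short: ", path)

  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop) || first_pop < 3L) {
    stop("Genepop parse error: no POP line after locus names in ", path)
  }
  # locus names: lines 2..(first_pop-1), possibly comma-separated
  locus_names <- trimws(unlist(strsplit(lines[2:(first_pop - 1L)], ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  J <- length(locus_names)

  ind_lines <- which(!is_pop & seq_along(lines) > first_pop)
  pop_id <- cumsum(is_pop)[ind_lines]
  ids <- character(0)
  geno_tokens <- vector("list", length(ind_lines))
  for (r in seq_along(ind_lines)) {
    ln <- lines[ind_lines[r]]
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma < 0L) {
      stop("Genepop parse error at line ", lineno[ind_lines[r]],
           ": expected '<id> , <genotypes>'")
    }
    ids[r] <- trimws(substr(ln, 1L, comma - 1L))
    toks <- strsplit(trimws(substr(ln, comma + 1L, nchar(ln))), "[ \t]+")[[1L]]
    if (length(toks) != J) {
      stop("Genepop parse error at line ", lineno[ind_lines[r]], ": ",
           length(toks), " genotypes for ", J, " loci")
    }
    geno_tokens[[r]] <- toks
  }
  N <- length(ind_lines)
  if (N == 0L) stop("Genepop file has no individuals: ", path)
  widths <- unique(nchar(unlist(geno_tokens)))
  if (length(widths) != 1L || !(widths %in% c(4L, 6L))) {
    stop("Genepop format error: inconsistent allele-code width (tokens of ",
         paste(sort(widths), collapse = "/"), " characters)")
  }
  aw <- widths / 2L # allele-code width
  miss_code <- strrep("0", aw)

  a1 <- matrix(substr(unlist(geno_tokens), 1L, aw), nrow = N, byrow = TRUE)
  a2 <- matrix(substr(unlist(geno_tokens), aw + 1L, 2L * aw), nrow = N, byrow = TRUE)
  missing <- a1 == miss_code | a2 == miss_code
  a1[missing] <- NA
  a2[missing] <- NA

  build_from_allele_pairs(a1, a2, missing, ids, locus_names,
                          pop = factor(paste0("pop", pop_id)))
}

# assemble a diploid genotype_matrix from two N x J allele-label matrices
build_from_allele_pairs <- function(a1, a2, missing, ids, locus_names,
                                    pop = NULL, allow_monomorphic = FALSE) {
  J <- ncol(a1)
  N <- nrow(a1)
  alleles <- lapply(seq_len(J), function(j) {
    sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
  })
  if (any(lengths(alleles) == 0L)) {
    stop("locus ", locus_names[which(lengths(alleles) == 0L)[1L]],
         " has no observed genotypes")
  }
  loci <- rep(seq_len(J), lengths(alleles))
  P <- length(loci)
  offs <- c(0L, cumsum(lengths(alleles)))
  tab <- matrix(0L, N, P)
  for (j in seq_len(J)) {
    c1 <- offs[j] + match(a1[, j], alleles[[j]])
    c2 <- offs[j] + match(a2[, j], alleles[[j]])
    ok <- which(!missing[, j])
    for (i in ok) {
      tab[i, c1[i]] <- tab[i, c1[i]] + 1L
      tab[i, c2[i]] <- tab[i, c2[i]] + 1L
    }
  }
  g <- genotype_matrix(tab, loci, ploidy = 2L, ids = ids,
                       locus_names = locus_names,
                       allele_names = unlist(alleles),
                       missing = missing,
                       allow_monomorphic = allow_monomorphic)
  if (!is.null(pop)) attr(g, "pop") <- pop
  g
}

#' Write a Genepop file
#'
#' Writes a diploid [genotype_matrix] in Genepop format using 3-digit allele
#' codes. Allele labels that are not small integers are recoded to their
#' within-locus index. Missing genotypes are written as `000000`.
#'
#' @param x a diploid [genotype_matrix].
#' @param path output file path.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "hwclust export") {
  if (x$ploidy != 2L) stop("Genepop output requires diploid data")
  codes <- genepop_allele_codes(x)
  rows <- vapply(seq_len(n_ind(x)), function(i) {
    toks <- vapply(seq_len(n_loci(x)), function(j) {
      if (x$missing[i, j]) return("000000")
      cols <- which(x$loci == j)
      cnt <- x$tab[i, cols]
      paste(rep(codes[cols], cnt), collapse = "")
    }, character(1L))
    paste0(x$ids[i], " , ", paste(toks, collapse = " "))
  }, character(1L))
  pop <- attr(x, "pop")
  if (is.null(pop)) pop <- factor(rep(1L, n_ind(x)))
  out <- c(title, x$locus_names)
  for (lev in levels(pop)) out <- c(out, "POP", rows[pop == lev])
  writeLines(out, path)
  invisible(path)
}

genepop_allele_codes <- function(x) {
  suppressWarnings(num <- as.integer(x$allele_names))
  if (anyNA(num) || any(num < 1L | num > 999L)) {
    num <- unlist(lapply(tabulate(x$loci), seq_len), use.names = FALSE)
  }
  sprintf("%03d", num)
}

#' Read a STRUCTURE-format text file
#'
#' Supports the one-row-per-individual dialect (ploidy consecutive columns
#' per locus) and the default multi-row dialect (`ploidy` rows per
#' individual, one column per locus). The first column holds individual ids;
#' `n_extra_cols` additional leading columns (e.g. pop data) are skipped.
#'
#' @param path path to the file.
#' @param ploidy allele copies per locus (default 2).
#' @param one_row_per_individual `TRUE` for the single-row dialect.
#' @param missing_code allele code marking missing data (default -9).
#' @param n_extra_cols extra columns between the id and the genotypes.
#' @param locus_names optional locus labels; default `loc1..locJ`.
#' @return A [genotype_matrix].
#' @export
read_structure <- function(path, ploidy = 2L, one_row_per_individual = FALSE,
                           missing_code = -9L, n_extra_cols = 0L,
                           locus_names = NULL) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  ids_col <- raw[[1L]]
  dat <- as.matrix(raw[, -seq_len(1L + n_extra_cols), drop = FALSE])
  ploidy <- as.integer(ploidy)

  if (one_row_per_individual) {
    if (ncol(dat) %% ploidy != 0L) {
      stop("STRUCTURE format error: ", ncol(dat),
           " genotype columns not divisible by ploidy ", ploidy)
    }
    J <- ncol(dat) %/% ploidy
    N <- nrow(dat)
    ids <- ids_col
    # alleles of locus j are adjacent columns (j-1)*ploidy + 1..ploidy
    allele_mat <- array(dat, dim = c(N, ploidy, J))
    allele_rows <- matrix(aperm(allele_mat, c(2L, 1L, 3L)), nrow = N * ploidy)
  } else {
    if (nrow(dat) %% ploidy != 0L) {
      stop("STRUCTURE format error: ", nrow(dat),
           " rows not divisible by ploidy ", ploidy)
    }
    N <- nrow(dat) %/% ploidy
    J <- ncol(dat)
    ids <- ids_col[seq(1L, by = ploidy, length.out = N)]
    allele_rows <- dat # (N*ploidy) x J, rows grouped by individual
  }

  locus_names <- locus_names %||% paste0("loc", seq_len(J))
  allele_rows[allele_rows == as.character(missing_code)] <- NA
  ind_of_row <- rep(seq_len(N), each = ploidy)
  missing <- matrix(FALSE, N, J)
  for (j in seq_len(J)) {
    na_rows <- is.na(allele_rows[, j])
    missing[, j] <- tapply(na_rows, ind_of_row, any)
  }
  # drop partially-typed genotypes entirely (missing-genotype semantics)
  for (j in seq_len(J)) allele_rows[missing[ind_of_row, j], j] <- NA

  alleles <- lapply(seq_len(J), function(j) {
    labs <- unique(stats::na.omit(allele_rows[, j]))
    suppressWarnings(num <- as.numeric(labs))
    if (!anyNA(num)) labs[order(num)] else sort(labs)
  })
  if (any(lengths(alleles) == 0L)) {
    stop("locus ", locus_names[which(lengths(alleles) == 0L)[1L]],
         " has no observed genotypes")
  }
  loci <- rep(seq_len(J), lengths(alleles))
  offs <- c(0L, cumsum(lengths(alleles)))
  tab <- matrix(0L, N, length(loci))
  for (j in seq_len(J)) {
    col <- offs[j] + match(allele_rows[, j], alleles[[j]])
    ok <- which(!is.na(col))
    for (r in ok) tab[ind_of_row[r], col[r]] <- tab[ind_of_row[r], col[r]] + 1L
  }
  genotype_matrix(tab, loci, ploidy = ploidy, ids = ids,
                  locus_names = locus_names, allele_names = unlist(alleles),
                  missing = missing)
}

#' Write a STRUCTURE-format text file
#'
#' Writes the multi-row dialect (`ploidy` rows per individual, one column per
#' locus). Allele labels must be integer-like; otherwise they are recoded to
#' their within-locus index. Missing genotypes are written as `missing_code`.
#'
#' @inheritParams read_structure
#' @param x a [genotype_matrix].
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, missing_code = -9L) {
  suppressWarnings(num <- as.integer(x$allele_names))
  if (anyNA(num)) num <- unlist(lapply(tabulate(x$loci), seq_len), use.names = FALSE)
  rows <- character(n_ind(x) * x$ploidy)
  r <- 0L
  for (i in seq_len(n_ind(x))) {
    per_locus <- lapply(seq_len(n_loci(x)), function(j) {
      if (x$missing[i, j]) return(rep(missing_code, x$ploidy))
      cols <- which(x$loci == j)
      rep(num[cols], x$tab[i, cols])
    })
    allele_tab <- do.call(cbind, per_locus) # ploidy x J
    for (p in seq_len(x$ploidy)) {
      r <- r + 1L
      rows[r] <- paste(c(x$ids[i], allele_tab[p, ]), collapse = " ")
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read / write an allele-count CSV matrix
#'
#' The CSV dialect has a header `id,<locus>.<allele>,...` and one row per
#' individual with integer allele copy counts. An all-zero locus block
#' encodes a missing genotype; any other block must sum to the ploidy.
#'
#' @param path file path.
#' @param ploidy allele copies per locus (default 2).
#' @param allow_monomorphic passed to [genotype_matrix()].
#' @return A [genotype_matrix].
#' @export
read_counts_csv <- function(path, ploidy = 2L, allow_monomorphic = FALSE) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1L] != "id") stop("counts CSV must start with an 'id' column")
  ids <- as.character(d[[1L]])
  tab <- as.matrix(d[, -1L, drop = FALSE])
  cols <- colnames(tab)
  dot <- regexpr("\\.[^.]*$", cols)
  if (any(dot < 0L)) stop("counts CSV header columns must be '<locus>.<allele>'")
  locus_lab <- substr(cols, 1L, dot - 1L)
  allele_lab <- substring(cols, dot + 1L)
  locus_names <- unique(locus_lab)
  loci <- match(locus_lab, locus_names)
  if (is.unsorted(loci)) stop("counts CSV columns must be grouped by locus")
  genotype_matrix(tab, loci, ploidy = ploidy, ids = ids,
                  locus_names = locus_names, allele_names = allele_lab,
                  allow_monomorphic = allow_monomorphic)
}

#' @rdname read_counts_csv
#' @param x a [genotype_matrix].
#' @export
write_counts_csv <- function(x, path) {
  d <- data.frame(id = x$ids, x$tab, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read biallelic sites from a VCF
#'
#' Ingests GT fields of biallelic sites only; multi-allelic sites are skipped
#' with a message reporting the skip count. `./.` genotypes become missing.
#' Requires the vcfR package.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return A diploid [genotype_matrix] with REF/ALT allele labels; the number
#'   of skipped non-biallelic sites is attached as attribute `n_skipped`.
#' @export
read_vcf_biallelic <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_biallelic() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  n_skip <- sum(!bi)
  if (!any(bi)) stop("VCF contains no biallelic sites: ", path)
  if (n_skip > 0L) message("skipped ", n_skip, " non-biallelic site(s)")
  v <- v[bi, ]
  gt <- vcfR::extract.gt(v, element = "GT") # sites x individuals
  fix <- vcfR::getFIX(v)
  locus_names <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                        paste(fix[, "CHROM"], fix[, "POS"], sep = "_"),
                        fix[, "ID"])
  locus_names <- make.unique(as.character(locus_names))
  J <- nrow(gt)
  N <- ncol(gt)
  core <- sub(":.*$", "", t(gt)) # individuals x sites
  a1 <- sub("^([^/|]*)[/|].*$", "\\1", core)
  a2 <- sub("^[^/|]*[/|](.*)$", "\\1", core)
  missing <- is.na(core) | a1 == "." | a2 == "." | a1 == core
  alt <- as.integer(a1 == "1") + as.integer(a2 == "1")
  alt[missing] <- 0L
  ref <- 2L - alt
  ref[missing] <- 0L
  tab <- matrix(0L, N, 2L * J)
  tab[, seq(1L, 2L * J, by = 2L)] <- ref
  tab[, seq(2L, 2L * J, by = 2L)] <- alt
  allele_names <- as.vector(rbind(fix[, "REF"], fix[, "ALT"]))
  g <- genotype_matrix(tab, rep(seq_len(J), each = 2L), ploidy = 2L,
                       ids = colnames(gt), locus_names = locus_names,
                       allele_names = allele_names, missing = missing,
                       allow_monomorphic = TRUE)
  attr(g, "n_skipped") <- n_skip
  g
}
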