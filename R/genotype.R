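#' Construct a genotype dosage matrix
#'
#' A `genotype_matrix` holds alternate-allele dosages for `n` samples by
#' `m` variants. Dosages are coded 0 (homozygous reference), 1
#' (heterozygous), 2 (homozygous alternate); missing calls are `NA`.
#' After mean imputation cells may be fractional; the imputation mode is
#' recorded in the object.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#'   Non-missing values must lie in \{0, 1, 2\} unless `imputed` is set.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to rownames of `dosages` or `s1..sn`.
#' @param variants data.frame with columns `id`, `chromosome`, `position`
#'   (1-based) and optionally `ref`, `alt`; defaults are built from
#'   column names of `dosages`.
#' @param imputed `NA` if the matrix has not been imputed, otherwise the
#'   imputation mode (`"mean"` or `"mode"`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `sample_ids`, `variants`, `imputed`.
#' @export
genotype_matrix <- function(dosages, sample_ids = NULL, variants = NULL,
                            imputed = NA_character_) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) {
    stop("length(sample_ids) must equal nrow(dosages)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (is.null(variants)) {
    ids <- colnames(dosages)
    if (is.null(ids)) ids <- paste0("v", seq_len(m))
    variants <- data.frame(id = ids, chromosome = "1",
                           position = seq_len(m),
                           stringsAsFactors = FALSE)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!all(c("id", "chromosome", "position") %in% names(variants))) {
    stop("variants must have columns id, chromosome, position")
  }
  if (nrow(variants) != m) stop("nrow(variants) must equal ncol(dosages)")
  if (any(!nzchar(variants$id))) stop("variant ids must be non-empty")
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant ids: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  }
  if (any(!is.na(variants$position) & variants$position < 1)) {
    stop("variant positions must be >= 1")
  }
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (is.na(imputed) && !all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid dosage %s at sample %s, variant %s (must be 0/1/2/NA)",
                 format(dosages[bad[1], bad[2]]),
                 sample_ids[bad[1]], variants$id[bad[2]]))
  }
  dimnames(dosages) <- list(sample_ids, variants$id)
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 variants = variants, imputed = imputed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants; %d missing cells; imputed: %s\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages)),
              ifelse(is.na(x$imputed), "no", x$imputed)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Accept either a genotype_matrix or a bare numeric matrix.
dosage_matrix <- function(g) {
  if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
}

variant_ids <- function(g) {
  if (inherits(g, "genotype_matrix")) g$variants$id
  else colnames(as.matrix(g)) %||% paste0("v", seq_len(ncol(as.matrix(g))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a phenotype vector
#'
#' @param values numeric vector of phenotype values (`NA` allowed for
#'   missing); for `task = "binary"` the non-missing values must be 0/1.
#' @param task `"continuous"` or `"binary"`.
#' @param sample_ids optional sample identifiers (names of `values` by
#'   default).
#' @return A numeric vector of class `phenotype_vector` with attribute
#'   `task`.
#' @export
phenotype_vector <- function(values, task = c("continuous", "binary"),
                             sample_ids = NULL) {
  task <- match.arg(task)
  values <- as.numeric(values)
  if (task == "binary") {
    bad <- !is.na(values) & !values %in% c(0, 1)
    if (any(bad)) stop("binary phenotype values must be 0/1/NA")
  }
  if (!is.null(sample_ids)) names(values) <- sample_ids
  structure(values, task = task, class = "phenotype_vector")
}

pheno_task <- function(y, default = "continuous") {
  attr(y, "task") %||% default
}

missing_tokens <- c("NA", "", ".")

#' Read a genotype dosage TSV file
#'
#' Expected layout: tab-separated, header row of variant ids with a
#' leading sample-id column, cells in \{0, 1, 2\} or a missing token
#' (`NA`, empty, or `.`).
#'
#' @param path path to the TSV file.
#' @return A [genotype_matrix].
#' @seealso [write_dosage_tsv()]
#' @export
read_dosage_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty dosage file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 2) stop("dosage TSV needs a sample-id column and at least one variant")
  vids <- header[-1]
  m <- length(vids)
  body <- fields[-1]
  n <- length(body)
  sample_ids <- character(n)
  dos <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != m + 1) {
      stop(sprintf("row %d has %d fields, expected %d", i + 1, length(row), m + 1))
    }
    sample_ids[i] <- row[1]
    cells <- row[-1]
    miss <- cells %in% missing_tokens
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(!miss & (is.na(vals) | !vals %in% c(0, 1, 2)))
    if (length(bad)) {
      stop(sprintf("invalid dosage '%s' at sample %s, variant %s",
                   cells[bad[1]], row[1], vids[bad[1]]))
    }
    vals[miss] <- NA_real_
    dos[i, ] <- vals
  }
  genotype_matrix(dos, sample_ids = sample_ids,
                  variants = data.frame(id = vids, chromosome = "1",
                                        position = seq_len(m),
                                        stringsAsFactors = FALSE))
}

#' Write a genotype dosage TSV file
#'
#' Missing cells are written as `NA`. Inverse of [read_dosage_tsv()] on
#' the (dosages, missing mask, ids) triple.
#'
#' @param g a [genotype_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosages
  header <- paste(c("sample_id", g$variants$id), collapse = "\t")
  rows <- vapply(seq_len(nrow(dos)), function(i) {
    cells <- ifelse(is.na(dos[i, ]), "NA",
                    format(dos[i, ], trim = TRUE, scientific = FALSE))
    paste(c(g$sample_ids[i], cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a PLINK .raw (recode A) file
#'
#' Layout produced by `plink --recode A`: whitespace-separated columns
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP allele
#' (`rsid_A`); dosages in \{0, 1, 2\}, missing `NA`. The trailing
#' `_allele` suffix is stripped from variant ids. A PHENOTYPE value of
#' `-9` or `NA` is treated as missing.
#'
#' @param path path to the .raw file.
#' @param with_phenotype if `TRUE`, return
#'   `list(genotypes =, phenotype =)` with the PHENOTYPE column as a
#'   [phenotype_vector]; otherwise just the [genotype_matrix].
#' @return A [genotype_matrix], or a list when `with_phenotype = TRUE`.
#' @export
read_plink_raw <- function(path, with_phenotype = FALSE) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (ncol(df) < 6 || !identical(names(df)[1:6], need)) {
    stop(".raw header must start with: ", paste(need, collapse = " "))
  }
  if (ncol(df) < 7) stop(".raw file contains no SNP columns")
  snp_cols <- names(df)[-(1:6)]
  vids <- sub("_[^_]*$", "", snp_cols)
  dos <- as.matrix(df[, -(1:6), drop = FALSE])
  storage.mode(dos) <- "double"
  g <- genotype_matrix(dos, sample_ids = as.character(df$IID),
                       variants = data.frame(id = vids, chromosome = NA_character_,
                                             position = NA_integer_,
                                             stringsAsFactors = FALSE))
  if (!with_phenotype) return(g)
  ph <- as.numeric(df$PHENOTYPE)
  ph[!is.na(ph) & ph == -9] <- NA_real_
  task <- if (all(is.na(ph) | ph %in% c(0, 1))) "binary" else "continuous"
  list(genotypes = g,
       phenotype = phenotype_vector(ph, task, sample_ids = as.character(df$IID)))
}

#' Read genotype dosages from a VCF file
#'
#' Dosage is the alternate-allele count in the GT field; `./.` and
#' half-calls (e.g. `0/.`) are missing. Multi-allelic records are
#' skipped with a warning. Variants with ID `.` are named
#' `chrom:pos`.
#'
#' @param path path to a VCF (v4.x) file, plain or bgzipped.
#' @return A [genotype_matrix].
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  fmt <- v@gt[, 1]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    stop("VCF records lack a GT format field")
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipped %d multi-allelic record(s)", sum(multi)))
  }
  keep <- which(!multi)
  if (!length(keep)) stop("no biallelic records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  # allele counting; any missing allele makes the dosage missing
  count_alt <- function(s) {
    if (is.na(s)) return(NA_real_)
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == ".")) return(NA_real_)
    sum(a != "0")
  }
  dos <- matrix(vapply(gt, count_alt, numeric(1)),
                nrow = nrow(gt), ncol = ncol(gt))
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[keep, "CHROM"][noid], ":", fix[keep, "POS"][noid])
  genotype_matrix(t(dos),
                  sample_ids = colnames(gt),
                  variants = data.frame(id = ids,
                                        chromosome = fix[keep, "CHROM"],
                                        position = as.integer(fix[keep, "POS"]),
                                        ref = fix[keep, "REF"],
                                        alt = fix[keep, "ALT"],
                                        stringsAsFactors = FALSE))
}

#' Read a phenotype TSV file
#'
#' Two tab-separated columns: sample id and value, no header.
#'
#' @param path path to the file.
#' @param task `"continuous"` or `"binary"`.
#' @return A [phenotype_vector] named by sample id.
#' @export
read_phenotype_tsv <- function(path, task = c("continuous", "binary")) {
  task <- match.arg(task)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample_id", "value"),
                          stringsAsFactors = FALSE,
                          na.strings = missing_tokens)
  phenotype_vector(df$value, task, sample_ids = df$sample_id)
}

#' Impute missing dosages
#'
#' Per-variant imputation: `mean` replaces missing cells with the
#' variant's mean dosage (possibly fractional); `mode` with its most
#' frequent dosage, ties broken towards the lowest dosage value.
#' Non-missing cells are never changed.
#'
#' @param g a [genotype_matrix].
#' @param mode `"mean"` or `"mode"`.
#' @return A [genotype_matrix] with no missing cells and `imputed` set.
#' @export
impute_missing <- function(g, mode = c("mean", "mode")) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosages
  miss_col <- colSums(is.na(dos))
  all_missing <- which(miss_col == nrow(dos))
  if (length(all_missing)) {
    stop("variant with no observed dosages: ", g$variants$id[all_missing[1]])
  }
  for (j in which(miss_col > 0)) {
    x <- dos[, j]
    fill <- if (mode == "mean") {
      mean(x, na.rm = TRUE)
    } else {
      tab <- table(x)
      vals <- as.numeric(names(tab))
      # which.max on the table keeps the first (lowest-dosage) maximum
      vals[which.max(tab)]
    }
    dos[is.na(x), j] <- fill
  }
  g$dosages <- dos
  g$imputed <- mode
  g
}
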