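#' Construct a genotype dosage matrix
#'
#' A `genotype_matrix` holds an individuals x markers matrix of biallelic
#' allele dosages with a declared encoding. Two integer encodings are
#' accepted, `"MINUS1_0_1"` and `"ZERO_1_2"`; `"CONTINUOUS"` arises only
#' after imputation, when missing cells are replaced by neighbour means.
#'
#' @param dosage numeric matrix with individual ids as row names and marker
#'   ids as column names; `NA` marks missing dosages.
#' @param encoding one of `"MINUS1_0_1"`, `"ZERO_1_2"`, `"CONTINUOUS"`.
#' @param base_encoding for `"CONTINUOUS"` matrices, the integer encoding the
#'   values originated from (determines the dosage scale); ignored otherwise.
#' @return an object of class `genotype_matrix` with fields `dosage`,
#'   `encoding` and `base_encoding`.
#' @export
genotype_matrix <- function(dosage,
                            encoding = c("ZERO_1_2", "MINUS1_0_1", "CONTINUOUS"),
                            base_encoding = NULL) {
  encoding <- match.arg(encoding)
  if (!is.matrix(dosage) || !is.numeric(dosage))
    stop("'dosage' must be a numeric matrix")
  if (nrow(dosage) < 1L || ncol(dosage) < 1L)
    stop("genotype matrix must have at least 1 individual and 1 marker")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("'dosage' must carry individual ids as rownames and marker ids as colnames")
  dup_i <- rownames(dosage)[duplicated(rownames(dosage))]
  if (length(dup_i))
    stop("duplicate individual id: ", dup_i[1L])
  dup_m <- colnames(dosage)[duplicated(colnames(dosage))]
  if (length(dup_m))
    stop("duplicate marker id: ", dup_m[1L])
  vals <- dosage[!is.na(dosage)]
  if (encoding == "MINUS1_0_1") {
    if (length(vals) && !all(vals %in% c(-1, 0, 1)))
      stop("MINUS1_0_1 encoding admits only {-1, 0, 1}")
    base_encoding <- NULL
  } else if (encoding == "ZERO_1_2") {
    if (length(vals) && !all(vals %in% c(0, 1, 2)))
      stop("ZERO_1_2 encoding admits only {0, 1, 2}")
    base_encoding <- NULL
  } else {
    if (is.null(base_encoding)) base_encoding <- "ZERO_1_2"
    base_encoding <- match.arg(base_encoding, c("ZERO_1_2", "MINUS1_0_1"))
    rng <- if (base_encoding == "ZERO_1_2") c(0, 2) else c(-1, 1)
    if (length(vals) && (min(vals) < rng[1L] || max(vals) > rng[2L]))
      stop("CONTINUOUS dosages must lie within [", rng[1L], ", ", rng[2L], "]")
  }
  structure(list(dosage = dosage, encoding = encoding,
                 base_encoding = base_encoding),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers, encoding %s\n",
              nrow(x$dosage), ncol(x$dosage), x$encoding))
  n_miss <- sum(is.na(x$dosage))
  cat(sprintf("  missing cells: %d (%.2f%%)\n", n_miss,
              100 * n_miss / length(x$dosage)))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`.
#' @export
individuals <- function(g) rownames(g$dosage)

#' @rdname genotype_matrix
#' @export
markers <- function(g) colnames(g$dosage)

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# Dosages on the {0,1,2} reference-count scale, whatever the declared encoding.
dosage_012 <- function(g) {
  shift_from <- if (g$encoding == "CONTINUOUS") g$base_encoding else g$encoding
  if (identical(shift_from, "MINUS1_0_1")) g$dosage + 1 else g$dosage
}

# Row/column subsetting that preserves class, encoding and dimnames.
subset_genotypes <- function(g, individuals = NULL, markers = NULL) {
  d <- g$dosage
  if (!is.null(individuals)) {
    missing_ids <- setdiff(individuals, rownames(d))
    if (length(missing_ids))
      stop("individuals absent from genotype matrix: ",
           paste(utils::head(missing_ids, 5L), collapse = ", "))
    d <- d[individuals, , drop = FALSE]
  }
  if (!is.null(markers)) {
    missing_mk <- setdiff(markers, colnames(d))
    if (length(missing_mk))
      stop("markers absent from genotype matrix: ",
           paste(utils::head(missing_mk, 5L), collapse = ", "))
    d <- d[, markers, drop = FALSE]
  }
  genotype_matrix(d, g$encoding, base_encoding = g$base_encoding)
}

#' Read a genotype dosage matrix from TSV
#'
#' Expects a tab-separated file whose header row lists marker ids, whose first
#' column holds individual ids, and whose cells are integer dosages or the
#' token `NA`. The encoding is auto-detected: `MINUS1_0_1` if any cell equals
#' -1, otherwise `ZERO_1_2`. A file containing only {0, 1} is ambiguous and
#' defaults to `ZERO_1_2` with a warning. A file mixing -1 and 2 is rejected
#' as inconsistently encoded.
#'
#' @param path path to the TSV file.
#' @return a [genotype_matrix].
#' @export
read_genotype_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L)
    stop("genotype file must have an id column and at least one marker column")
  ids <- dt[[1L]]
  mk <- colnames(dt)[-1L]
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric dosage cell in ", path)
  bad <- which(!is.na(m) & !(m %in% c(-1, 0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(m))
    stop(sprintf("invalid dosage %s at row %d (individual %s), column %s",
                 format(m[bad[1L]]), rc[1L], ids[rc[1L]], mk[rc[2L]]))
  }
  has_m1 <- any(m == -1, na.rm = TRUE)
  has_2 <- any(m == 2, na.rm = TRUE)
  if (has_m1 && has_2)
    stop("inconsistent encoding: file contains both -1 and 2")
  if (has_m1) {
    enc <- "MINUS1_0_1"
  } else {
    if (!has_2 && any(!is.na(m)))
      warning("dosages contain only {0, 1}; encoding is ambiguous, ",
              "defaulting to ZERO_1_2")
    enc <- "ZERO_1_2"
  }
  rownames(m) <- ids
  colnames(m) <- mk
  genotype_matrix(m, enc)
}

#' Write a genotype matrix to TSV
#'
#' Inverse of [read_genotype_matrix()]: header `id` + marker ids, one row per
#' individual, `NA` for missing cells.
#'
#' @param g a [genotype_matrix].
#' @param path output file path.
#' @export
write_genotype_matrix <- function(g, path) {
  df <- data.frame(id = individuals(g), g$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Convert between integer genotype encodings
#'
#' Applies the affine map between the two accepted integer codes:
#' `ZERO_1_2` dosage v maps to v - 1 under `MINUS1_0_1` and vice versa.
#' Missing cells are preserved; converting to the current encoding is the
#' identity.
#'
#' @param g a [genotype_matrix] with an integer encoding.
#' @param target `"MINUS1_0_1"` or `"ZERO_1_2"`.
#' @return a [genotype_matrix] in the target encoding.
#' @export
convert_encoding <- function(g, target) {
  if (identical(target, "CONTINUOUS"))
    stop("invalid target encoding: CONTINUOUS is produced by imputation only")
  target <- match.arg(target, c("ZERO_1_2", "MINUS1_0_1"))
  if (g$encoding == "CONTINUOUS")
    stop("cannot convert a CONTINUOUS matrix to an integer encoding")
  if (g$encoding == target) return(g)
  shift <- if (target == "MINUS1_0_1") -1 else 1
  genotype_matrix(g$dosage + shift, target)
}

#' Restrict two genotype matrices to their shared markers
#'
#' Selection candidates can only be predicted with markers matching those the
#' training population was genotyped with. Both matrices are restricted to the
#' intersection of their marker sets, in the training matrix's marker order.
#'
#' @param train training-population [genotype_matrix].
#' @param cand candidate-population [genotype_matrix].
#' @param min_overlap minimum acceptable fraction of training markers present
#'   in the candidate set (default 0.5).
#' @return list with components `train`, `cand` (both restricted), and
#'   `overlap` (shared fraction of the training marker set).
#' @export
match_markers <- function(train, cand, min_overlap = 0.5) {
  shared <- intersect(markers(train), markers(cand))
  if (length(shared) == 0L)
    stop("incompatible populations: no shared markers between training and candidates")
  overlap <- length(shared) / length(markers(train))
  if (overlap < min_overlap)
    stop(sprintf(paste0("marker overlap %.3f below the required minimum %.3f; ",
                        "candidates cannot be predicted reliably"),
                 overlap, min_overlap))
  shared <- markers(train)[markers(train) %in% shared]  # training order
  list(train = subset_genotypes(train, markers = shared),
       cand = subset_genotypes(cand, markers = shared),
       overlap = overlap)
}

#' Read a list of individual names
#'
#' One name per line; blank lines and `#` comments are ignored.
#'
#' @param path path to the list file.
#' @return character vector of unique individual names.
#' @export
read_individual_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  members <- lines[nzchar(lines)]
  if (length(members) == 0L)
    stop("individual list ", path, " is empty")
  dup <- members[duplicated(members)]
  if (length(dup))
    stop("duplicate individual in list: ", dup[1L])
  members
}
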