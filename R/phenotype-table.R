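#' Plot-level phenotype tables
#'
#' A phenotype table holds one row per field plot: trial id, genotype id,
#' optional replication and block labels, the trial design, and one numeric
#' column per trait. Recognised designs are `RCBD`, `ALPHA_LATTICE`,
#' `AUGMENTED` and `UNKNOWN` (no experimental design recorded).
#'
#' @param df data.frame with columns `trial`, `genotype`, `design`, optional
#'   `replication` and `block`, and at least one numeric trait column.
#' @return the validated data.frame with class `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  required <- c("trial", "genotype", "design")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("phenotype table lacks required column(s): ",
         paste(miss, collapse = ", "))
  valid_designs <- c("RCBD", "ALPHA_LATTICE", "AUGMENTED", "UNKNOWN")
  bad <- setdiff(unique(df$design), valid_designs)
  if (length(bad))
    stop("unknown design label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(valid_designs, collapse = ", "), ")")
  if (!"replication" %in% names(df)) df$replication <- NA_character_
  if (!"block" %in% names(df)) df$block <- NA_character_
  if (length(trait_names(df)) == 0L)
    stop("phenotype table has no trait columns")
  df$trial <- as.character(df$trial)
  df$genotype <- as.character(df$genotype)
  class(df) <- unique(c("phenotype_table", class(df)))
  df
}

meta_columns <- c("trial", "genotype", "replication", "block", "design")

#' @rdname phenotype_table
#' @export
trait_names <- function(df) setdiff(names(df), meta_columns)

#' Read a plot-level phenotype table from CSV
#'
#' Required columns: `trial`, `genotype`, `design`; optional: `replication`,
#' `block`. Every other column is treated as a numeric trait. Missing values
#' are the token `NA`.
#'
#' @param path path to the CSV file.
#' @return a [phenotype_table].
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "NA",
                        stringsAsFactors = FALSE)
  for (tr in setdiff(names(df), meta_columns)) {
    v <- df[[tr]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (any(!is.na(v) & is.na(vn)))
        stop("non-numeric value in trait column '", tr, "'")
      df[[tr]] <- vn
    }
  }
  phenotype_table(df)
}

#' @rdname read_phenotype_table
#' @param df a [phenotype_table].
#' @export
write_phenotype_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, na = "NA",
                   quote = FALSE)
  invisible(path)
}
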