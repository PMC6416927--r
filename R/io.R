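# Plain-TSV readers/writers for the pipeline's tables. Every table is
# tab-separated with a mandatory header row and "NA" as the missing-value
# token, so intermediate results stay language-neutral and diff-able.

#' Write a data frame as TSV
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", na.strings = "NA", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Write a genes x items matrix as TSV (gene IDs in the first column)
#' @param mat Matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_state_matrix <- function(mat, path, id_col = "gene") {
  df <- data.frame(rownames(mat), as.data.frame(mat), check.names = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Read a genes x items matrix from TSV
#' @param path Input path.
#' @param id_col Identifier column (default: the first).
#' @return Matrix with gene IDs as rownames.
#' @export
read_state_matrix <- function(path, id_col = 1) {
  df <- read_tsv(path)
  ids <- df[[id_col]]
  df[[id_col]] <- NULL
  m <- as.matrix(df)
  rownames(m) <- ids
  m
}

#' Read and validate a duplicate-pair table
#'
#' @param path TSV with columns `geneA`, `geneB`, `event`
#'   (alpha/beta/gamma), `ds`.
#' @param events Allowed WGD event labels.
#' @return Validated data frame with a `pair` identifier column added when
#'   absent.
#' @export
read_pairs_table <- function(path, events = c("alpha", "beta", "gamma")) {
  d <- read_tsv(path)
  need <- c("geneA", "geneB", "event", "ds")
  if (!all(need %in% names(d))) {
    stop("pairs table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(d$geneA == d$geneB)) stop("a pair lists the same gene twice")
  if (any(!d$event %in% events)) {
    stop("unknown WGD event label(s): ",
         paste(setdiff(unique(d$event), events), collapse = ", "))
  }
  if (any(!is.finite(d$ds) | d$ds <= 0)) stop("ds must be positive")
  if (is.null(d$pair)) d$pair <- paste0("p", seq_len(nrow(d)))
  d
}
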