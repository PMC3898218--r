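# Per-gene attribute table: pairwise Ka/Ks, mRNA half-life, labels.

ka_cols <- c("ka_mit9313", "ka_ss120", "ka_cc9311")
ks_cols <- c("ks_mit9313", "ks_ss120", "ks_cc9311")

#' Construct a gene attribute table
#'
#' @param df data.frame with a \code{gene_id} column and any of:
#'   \code{ka_mit9313}, \code{ka_ss120}, \code{ka_cc9311} (pairwise Ka,
#'   substitutions/site, NA for missing orthologs), matching \code{ks_*},
#'   \code{half_life_min} (minutes, NA when unmeasured), \code{partition},
#'   \code{cog}, \code{deg_hit}, \code{pathway}, \code{is_ribosomal}.
#' @return The validated data.frame, class \code{gene_attributes}.
#' @export
gene_attributes <- function(df) {
  if (!"gene_id" %in% names(df)) stop("attribute table lacks gene_id")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in attribute table")
  for (col in c(ka_cols, ks_cols))
    if (!is.null(df[[col]]) && any(df[[col]] < 0, na.rm = TRUE))
      stop("validation error: negative substitution rate in ", col)
  if (!is.null(df$half_life_min) && any(df$half_life_min <= 0, na.rm = TRUE))
    stop("validation error: half_life_min must be positive")
  structure(df, class = c("gene_attributes", "data.frame"))
}

#' Read a gene attribute TSV
#'
#' @param path TSV path with header (see \code{\link{gene_attributes}}).
#' @return A \code{gene_attributes} data.frame.
#' @export
read_attributes <- function(path) {
  gene_attributes(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE,
                                    check.names = FALSE))
}

#' Write a gene attribute TSV
#'
#' @param attrs A \code{gene_attributes} data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_attributes <- function(attrs, path) {
  utils::write.table(attrs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

attr_ka_matrix <- function(attrs) {
  cols <- intersect(ka_cols, names(attrs))
  m <- as.matrix(attrs[, cols, drop = FALSE])
  rownames(m) <- attrs$gene_id
  m
}

attr_half_life <- function(attrs) {
  if (is.null(attrs$half_life_min)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(attrs$half_life_min, attrs$gene_id)
}
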