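#' Candidate tree tables
#'
#' Candidate trees are plain data.frames with columns `id` (character,
#' unique), `x`, `y` (meters), `height` (meters or `NA`) and `source` (one of
#' `"ALS"`, `"GSV"`, `"merged"`, `"filtered"`). All stage functions accept and
#' return this shape; extra columns are carried along where meaningful.
#'
#' @param id character ids (unique)
#' @param x,y planar coordinates, meters
#' @param height heights in meters (`NA` allowed)
#' @param source provenance tag
#' @param ... further columns recycled to length
#' @return a validated candidate data.frame
#' @export
treeCandidates <- function(id = character(), x = numeric(), y = numeric(),
                           height = NA_real_, source = "ALS", ...) {
  n <- length(id)
  df <- data.frame(id = as.character(id), x = as.numeric(x), y = as.numeric(y),
                   height = rep_len(as.numeric(height), n),
                   source = rep_len(as.character(source), n),
                   ..., stringsAsFactors = FALSE)
  validateCandidates(df)
  df
}

validateCandidates <- function(df) {
  need <- c("id", "x", "y", "height", "source")
  if (!all(need %in% names(df)))
    stop("candidates need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$id)) stop("candidate ids must be unique")
  if (nrow(df) && !all(is.finite(df$x) & is.finite(df$y)))
    stop("candidate positions must be finite")
  invisible(df)
}
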