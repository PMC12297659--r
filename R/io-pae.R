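# Predicted-aligned-error I/O in the AlphaFold consumer JSON format.
# Two dialects are accepted: the full-matrix form
# {"predicted_aligned_error": [[...]], "max_predicted_aligned_error": m}
# and the paired-index form {"residue1": [...], "residue2": [...],
# "distance": [...]}. Either may be wrapped in a one-element array.

#' Read a PAE matrix
#'
#' @param path path to an AlphaFold PAE JSON file.
#' @return A [pae_matrix]; entries above `max_pae` are clamped with a
#'   warning.
#' @export
read_pae <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.data.frame(js) && nrow(js) == 1L) js <- as.list(js[1, ])
  if (is.list(js) && is.null(names(js)) && length(js) == 1L) js <- js[[1]]
  js <- lapply(js, function(el)
    if (is.list(el) && length(el) == 1L && is.null(names(el))) el[[1]] else el)

  max_pae <- js[["max_predicted_aligned_error"]]
  if (is.null(max_pae)) max_pae <- 31.75
  max_pae <- as.numeric(max_pae)[1]

  mat_key <- intersect(c("predicted_aligned_error", "pae"), names(js))
  if (length(mat_key)) {
    m <- js[[mat_key[1]]]
    if (is.list(m)) m <- do.call(rbind, m)
    m <- as.matrix(m)
    if (nrow(m) != ncol(m))
      stop(sprintf("PAE matrix is not square (%d x %d)", nrow(m), ncol(m)),
           call. = FALSE)
  } else if (all(c("residue1", "residue2", "distance") %in% names(js))) {
    r1 <- as.integer(js$residue1); r2 <- as.integer(js$residue2)
    d <- as.numeric(js$distance)
    L <- max(r1, r2)
    if (length(d) != L * L)
      stop(sprintf("paired-index PAE does not reconstruct a square matrix (%d entries for L = %d)",
                   length(d), L), call. = FALSE)
    m <- matrix(NA_real_, L, L)
    m[cbind(r1, r2)] <- d
    if (anyNA(m))
      stop("paired-index PAE leaves unfilled entries", call. = FALSE)
  } else {
    stop("no recognizable PAE payload in ", path, call. = FALSE)
  }
  if (any(m > max_pae)) {
    warning(sprintf("%d PAE entries exceed max_pae = %.4g; clamped",
                    sum(m > max_pae), max_pae), call. = FALSE)
    m[m > max_pae] <- max_pae
  }
  pae_matrix(m, max_pae)
}

#' Write a PAE matrix (full-matrix dialect)
#'
#' @param pae a [pae_matrix].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pae <- function(pae, path) {
  stopifnot(inherits(pae, "pae_matrix"))
  jsonlite::write_json(
    list(predicted_aligned_error = unclass(pae),
         max_predicted_aligned_error = attr(pae, "max_pae")),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
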