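#' Construct a weighted gene signature
#'
#' A signature is an ordered set of genes with signed weights in
#' [-1, 1] excluding 0. The sign encodes the direction of regulation in
#' the fusion-positive state (positive = upregulated); the magnitude
#' encodes relative importance, with the strongest gene anchored at
#' |weight| = 1.
#'
#' @param gene character vector of unique gene identifiers.
#' @param weight numeric vector of weights in [-1, 1], none zero, with
#'   \code{max(abs(weight)) == 1}.
#' @param id optional identifier recorded in scoring metadata.
#' @return An object of class \code{"fusion_signature"}: a data.frame with
#'   columns \code{gene} and \code{weight}.
#' @export
new_signature <- function(gene, weight, id = "signature") {
  sig <- data.frame(gene = as.character(gene), weight = as.numeric(weight),
                    stringsAsFactors = FALSE)
  validate_signature(sig)
  attr(sig, "signature_id") <- id
  class(sig) <- c("fusion_signature", "data.frame")
  sig
}

validate_signature <- function(sig) {
  if (nrow(sig) == 0) stop("empty signature", call. = FALSE)
  if (anyDuplicated(sig$gene)) {
    stop("duplicate gene ids in signature: ",
         paste(unique(sig$gene[duplicated(sig$gene)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(sig$weight) | sig$weight == 0 |
                 abs(sig$weight) > 1 + 1e-12)
  if (length(bad)) {
    stop(sprintf(
      "signature weights must be nonzero and in [-1, 1]; offending row(s): %s",
      paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (abs(max(abs(sig$weight)) - 1) > 1e-9) {
    stop("signature must contain at least one weight of magnitude 1",
         call. = FALSE)
  }
  invisible(sig)
}

#' @export
print.fusion_signature <- function(x, ...) {
  n_up <- sum(x$weight > 0)
  cat(sprintf("<fusion_signature '%s'> %d genes (%d up, %d down)\n",
              attr(x, "signature_id") %||% "signature",
              nrow(x), n_up, nrow(x) - n_up))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... and %d more genes\n", nrow(x) - 6))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
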