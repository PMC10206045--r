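#' @keywords internal
"_PACKAGE"

#' @importFrom stats phyper rnorm rlnorm runif rpois setNames
#' @importFrom utils read.delim write.table head
NULL

# Closed vocabulary of family labels. "UC" marks structurally unclassifiable
# proteins awaiting phylogenetic label transfer.
GROUP_LABELS <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III", "UC")

DUP_MODES <- c("WGD", "TANDEM", "PROXIMAL", "TRANSPOSED", "DISPERSED")

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

wrky_log <- function(..., level = "INFO") {
  if (identical(getOption("wrkykit.quiet", TRUE), TRUE)) return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
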