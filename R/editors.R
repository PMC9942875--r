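## Base-editor models: which base is deaminated, to what, where in the
## protospacer, and under which PAM.

EDITOR_PRESETS <- list(
  "BE3-NGG"        = list(source_base = "C", product_base = "T",
                          window = c(4L, 9L), pam_pattern = "NGG"),
  "BE3.9max-NGN"   = list(source_base = "C", product_base = "T",
                          window = c(4L, 9L), pam_pattern = "NGN"),
  "YE1-BE4max-NGN" = list(source_base = "C", product_base = "T",
                          window = c(5L, 7L), pam_pattern = "NGN"),
  "ABE8e-NGN"      = list(source_base = "A", product_base = "G",
                          window = c(4L, 9L), pam_pattern = "NGN")
)

#' Base-editor configuration
#'
#' An editor is defined by its source/product base (C->T for cytidine
#' editors, A->G for adenine editors), its activity window in protospacer
#' coordinates (positions 1-20, PAM at 21-23), and its PAM pattern as an
#' IUPAC triplet. Four presets match widely used architectures: `"BE3-NGG"`
#' and `"BE3.9max-NGN"` (C->T, lenient window 4-9), `"YE1-BE4max-NGN"`
#' (C->T, narrowed window 5-7 of the engineered YE1 deaminase), and
#' `"ABE8e-NGN"` (A->G, window 4-9).
#'
#' @param name a preset name, or an arbitrary label when the remaining
#'   arguments are given explicitly
#' @param source_base `"C"` or `"A"`
#' @param product_base `"T"` or `"G"`
#' @param window inclusive protospacer position range, within 1..20
#' @param pam_pattern IUPAC triplet, e.g. `"NGG"`
#' @return object of class `EditorConfig`
#' @export
editor_config <- function(name, source_base = NULL, product_base = NULL,
                          window = NULL, pam_pattern = NULL) {
  if (is.null(source_base)) {
    preset <- EDITOR_PRESETS[[name]]
    if (is.null(preset))
      stop("unknown editor preset '", name, "'; presets: ",
           paste(names(EDITOR_PRESETS), collapse = ", "))
    source_base <- preset$source_base; product_base <- preset$product_base
    window <- preset$window; pam_pattern <- preset$pam_pattern
  }
  window <- as.integer(window)
  stopifnot(source_base %in% c("C", "A"), product_base %in% c("T", "G"),
            length(window) == 2L, window[1L] >= 1L,
            window[1L] <= window[2L], window[2L] <= 20L,
            nchar(pam_pattern) == 3L)
  structure(list(name = name, source_base = source_base,
                 product_base = product_base, window = window,
                 pam_pattern = pam_pattern),
            class = "EditorConfig")
}

#' @export
print.EditorConfig <- function(x, ...) {
  cat(sprintf("EditorConfig %s: %s->%s, window %d-%d, PAM %s\n", x$name,
              x$source_base, x$product_base, x$window[1L], x$window[2L],
              x$pam_pattern))
  invisible(x)
}
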