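# Classed conditions so callers can distinguish bad inputs from degenerate
# scenes (e.g. a slide with no tissue) without matching on message text.

nucseg_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "nucseg_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

input_error <- function(message) nucseg_error(message, "nucseg_input_error")
config_error <- function(message) nucseg_error(message, "nucseg_config_error")
no_tissue_error <- function(message) nucseg_error(message, "nucseg_no_tissue_error")
degenerate_stain_error <- function(message) nucseg_error(message, "nucseg_degenerate_stain_error")

assert_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    input_error(sprintf("`%s` must be an H x W x 3 array", arg))
  if (!all(is.finite(image)))
    input_error(sprintf("`%s` contains non-finite values", arg))
  if (min(image) < 0 || max(image) > 1)
    input_error(sprintf("`%s` must have values in [0, 1]", arg))
  invisible(image)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    input_error(sprintf("`%s` must be a logical matrix", arg))
  if (anyNA(mask))
    input_error(sprintf("`%s` contains NA", arg))
  invisible(mask)
}

assert_gray <- function(gray, arg = "gray") {
  if (!is.matrix(gray) || !is.numeric(gray))
    input_error(sprintf("`%s` must be a numeric matrix", arg))
  if (!all(is.finite(gray)))
    input_error(sprintf("`%s` contains non-finite values", arg))
  invisible(gray)
}
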