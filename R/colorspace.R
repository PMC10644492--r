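## Colour-space conversions. Standard sRGB -> HSV and sRGB -> CIELAB (D65)
## through grDevices; only the channel scales are fixed here so descriptor
## values are reproducible: H in [0, 360) degrees, S and V on 0..255,
## L* on [0, 100], a*/b* signed.

## n x 3 RGB (0..255) -> n x 3 HSV on the package scales.
.rgb_to_hsv <- function(rgb) {
  if (nrow(rgb) == 0) return(matrix(0, 0, 3, dimnames = list(NULL, c("H", "S", "V"))))
  h <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 255))
  out <- cbind(H = (h[, 1] * 360) %% 360, S = h[, 2] * 255, V = h[, 3] * 255)
  out
}

## n x 3 RGB (0..255) -> n x 3 Lab (D65).
.rgb_to_lab <- function(rgb) {
  if (nrow(rgb) == 0) return(matrix(0, 0, 3, dimnames = list(NULL, c("L", "a", "b"))))
  lab <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  colnames(lab) <- c("L", "a", "b")
  lab
}

## RGB array [h, w, 3] -> same-shape HSV array (zeros stay zero-valued black).
.rgb_array_to_hsv <- function(arr) {
  d <- dim(arr)
  flat <- matrix(arr, ncol = 3)
  hsv <- .rgb_to_hsv(flat)
  array(hsv, d)
}

.rgb_array_to_lab <- function(arr) {
  d <- dim(arr)
  flat <- matrix(arr, ncol = 3)
  lab <- .rgb_to_lab(flat)
  array(lab, d)
}
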