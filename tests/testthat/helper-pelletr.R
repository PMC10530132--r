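# shared fixture builders for the test suite

# digitized disk mask in an n x n matrix, center (cx, cy) in pixel-center
# coordinates, radius r in pixels
disk_mask <- function(r, cx, cy, n) {
  ix <- seq_len(n)
  outer((ix - cx)^2, (ix - cy)^2, "+") <= r^2
}

# grayscale image (dark foreground 0.2 on light background 0.9) from a mask
mask_to_image <- function(mask) {
  img <- matrix(0.9, nrow(mask), ncol(mask))
  img[mask] <- 0.2
  img
}

# the published screening data: design plus per-trial DCW means
table3_means <- function() load_fixture("table3")$dcw_mean

table3_printed <- function() attr(load_fixture("table3"), "printed_stats")

table4_sn <- function() load_fixture("table4")$sn
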