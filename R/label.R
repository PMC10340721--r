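# Canonical 26-connected labelling shared by the generator (ground truth) and
# the analysis side.  Components are relabelled 1..K ordered by (voxel count
# descending, first-voxel scan order ascending) so outputs are reproducible.

canonical_labels <- function(mask) {
  lab <- cc_label_3d(mask)
  k <- max(lab)
  if (k == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  first <- integer(k)
  seen <- lab != 0L
  # first occurrence in scan order for tie-breaking
  idx <- which(seen)
  first_occ <- idx[!duplicated(lab[idx])]
  first[lab[first_occ]] <- first_occ
  ord <- order(-sizes, first)
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  lab[seen] <- remap[lab[seen]]
  lab
}

# Per-label voxel counts of an integer label array with labels 1..K.
label_sizes <- function(lab) {
  k <- max(lab)
  if (k == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = k)
}

# Per-label centroids in voxel coordinates (1-based, rows = labels, cols z/y/x).
label_centroids <- function(lab) {
  k <- max(lab)
  if (k == 0L) return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  cen <- rowsum(idx + 0, l) / as.vector(table(factor(l, levels = seq_len(k))))
  colnames(cen) <- c("z", "y", "x")
  cen
}

# Box (Chebyshev) dilation by r voxels via separable moving sums; equivalent
# to r iterations of 26-neighbourhood dilation.
dilate_box <- function(mask, r) {
  if (r <= 0) return(mask)
  k <- rep(1, 2 * r + 1)
  out <- sep_conv_3d(mask * 1.0, k, k, k)
  out > 1e-9
}
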