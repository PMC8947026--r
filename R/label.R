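# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# diagonal-only neighbours come back as distinct labels; they are merged here
# with a small union-find over the label adjacency pairs.
label_components <- function(binary) {
  lab <- as.matrix(EBImage::bwlabel(binary * 1))
  n <- max(lab)
  if (n <= 1L) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  dr <- cbind(as.vector(lab[-nrow(lab), -ncol(lab)]), as.vector(lab[-1, -1]))
  dl <- cbind(as.vector(lab[-nrow(lab), -1]), as.vector(lab[-1, -ncol(lab)]))
  pairs <- rbind(dr, dl)
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  storage.mode(out) <- "integer"
  out
}

# Per-object features used by the object detection method: major-axis length
# (EBImage image moments) and mean grayscale intensity under the object mask.
object_features <- function(lab, gray) {
  n <- max(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  mom <- matrix(mom, nrow = n, ncol = length(mom) / n,
                dimnames = list(NULL, colnames(mom)))
  idx <- which(lab > 0)
  means <- vapply(split(gray[idx], lab[idx]), mean, numeric(1))
  data.frame(label = seq_len(n),
             major_axis_length_px = mom[, "m.majoraxis"],
             mean_masked_intensity = as.numeric(means[as.character(seq_len(n))]))
}
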