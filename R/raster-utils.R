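# Internal raster helpers built on EBImage::bwlabel.

# 8-connected component labelling. bwlabel() is 4-connected, so labels that
# touch diagonally are merged afterwards with a small union-find pass, then
# relabelled 1..k in order of first pixel in row-major (top-left) scan order.
label_components <- function(mask, connectivity = 8L) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  nmax <- max(lab)
  if (nmax > 0L && connectivity == 8L) {
    nr <- nrow(lab)
    nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]    # \ diagonal
    a2 <- lab[-1L, -nc]; b2 <- lab[-nr, -1L]    # / diagonal
    keep1 <- a1 > 0 & b1 > 0 & a1 != b1
    keep2 <- a2 > 0 & b2 > 0 & a2 != b2
    pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]),
                          cbind(a2[keep2], b2[keep2])))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(nmax)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1L])
        rb <- find(pairs[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nmax), find, integer(1L))
      lab[lab > 0] <- root[lab[lab > 0]]
    }
  }
  relabel_scan_order(lab)
}

# Relabel positive labels as 1..k by first occurrence in row-major order.
relabel_scan_order <- function(lab) {
  pos <- which(t(lab) > 0)                     # t(): row-major traversal
  if (length(pos) == 0L) {
    return(matrix(0L, nrow(lab), ncol(lab)))
  }
  vals <- t(lab)[pos]
  first <- vals[!duplicated(vals)]
  new <- integer(max(lab))
  new[first] <- seq_along(first)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- new[lab[lab > 0]]
  out
}

# Fill interior holes of a binary mask: background components (4-connected,
# the dual of 8-connected foreground) that do not touch the mask border.
fill_mask_holes <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  pad <- matrix(TRUE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- !(mask != 0)
  lab <- EBImage::imageData(EBImage::bwlabel(pad * 1))
  outside <- lab[1L, 1L]
  filled <- lab[2:(nr + 1L), 2:(nc + 1L)] != outside
  filled
}

crop_bbox <- function(mask) {
  rr <- range(which(rowSums(mask != 0) > 0))
  cc <- range(which(colSums(mask != 0) > 0))
  list(mask = mask[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE],
       r0 = rr[1L] - 1L, c0 = cc[1L] - 1L)   # 0-based offsets
}
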