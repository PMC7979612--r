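# 26-connected component labeling on 3D logical arrays.
# Frontier-vectorized BFS: each voxel enters a frontier exactly once, each
# frontier step does 26 vectorized neighbor lookups.

offsets_26 <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off[rowSums(abs(off)) > 0, , drop = FALSE]
}

# Unique 3D directions up to sign (13), used for GLCM/GLRLM scanning.
offsets_13 <- function() {
  off <- offsets_26()
  keep <- off[, 3] > 0 |
    (off[, 3] == 0 & off[, 2] > 0) |
    (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
  off[keep, , drop = FALSE]
}

#' Label 26-connected components of a 3D logical array
#'
#' @param mask 3D logical array.
#' @return Integer array of the same dimensions: 0 outside `mask`,
#'   component ids 1..k inside.
#' @keywords internal
label_components_26 <- function(mask) {
  d <- dim(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  lab <- array(0L, d)
  off <- offsets_26()
  lin_off <- off[, 1] + off[, 2] * nx + off[, 3] * nx * ny
  seeds <- which(mask)
  cur <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nbr <- integer(0)
      for (k in seq_len(26L)) {
        x <- co[, 1] + off[k, 1]; y <- co[, 2] + off[k, 2]; z <- co[, 3] + off[k, 3]
        ok <- x >= 1L & x <= nx & y >= 1L & y <= ny & z >= 1L & z <= nz
        if (any(ok)) nbr <- c(nbr, frontier[ok] + lin_off[k])
      }
      if (length(nbr)) {
        nbr <- unique(nbr)
        nbr <- nbr[mask[nbr] & lab[nbr] == 0L]
        lab[nbr] <- cur
        frontier <- nbr
      } else {
        frontier <- integer(0)
      }
    }
  }
  lab
}

# Retain only the largest 26-connected component of a logical array.
largest_component_26 <- function(mask) {
  lab <- label_components_26(mask)
  if (!any(lab > 0L)) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}
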