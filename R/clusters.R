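connectivity_offsets <- function(connectivity = 18) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = s == 1, "18" = s >= 1 & s <= 2,
                 "26" = s >= 1 & s <= 3,
                 stop_config("connectivity must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

## Label connected components of a set of voxels (linear indices into a
## grid of dimension `dim`). Deterministic: components are numbered in the
## order their lexicographically first voxel is encountered.
label_components <- function(lin_idx, dim, connectivity = 18) {
  labels <- integer(length(lin_idx))
  if (!length(lin_idx)) return(labels)
  ord <- order(lin_idx)
  lab_map <- array(0L, dim = dim)
  lab_map[lin_idx] <- -1L   # member, unlabeled
  off <- connectivity_offsets(connectivity)
  coords <- arrayInd(lin_idx, dim)
  next_lab <- 0L
  pos_of <- integer(prod(dim))   # linear index -> position in lin_idx
  pos_of[lin_idx] <- seq_along(lin_idx)
  for (s in ord) {
    start <- lin_idx[s]
    if (lab_map[start] != -1L) next
    next_lab <- next_lab + 1L
    queue <- s
    lab_map[start] <- next_lab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      labels[cur] <- next_lab
      cc <- coords[cur, ]
      for (k in seq_len(nrow(off))) {
        nb <- cc + off[k, ]
        if (any(nb < 1L) || any(nb > dim)) next
        nb_lin <- nb[1] + (nb[2] - 1L) * dim[1] +
          (nb[3] - 1L) * dim[1] * dim[2]
        if (lab_map[nb_lin] == -1L) {
          lab_map[nb_lin] <- next_lab
          queue <- c(queue, pos_of[nb_lin])
        }
      }
    }
  }
  labels
}

#' Form suprathreshold clusters from a statistic map
#'
#' Thresholds the uncorrected p map at the cluster-forming level inside
#' the mask and labels connected components under the chosen
#' connectivity (18-neighbour by default, the usual SPM convention).
#'
#' @param stat_map A [fit_marginal()] result carrying stack geometry, or
#'   a list with `p`, `wald`, `dim`, `voxel_index`.
#' @param cluster_forming_p Uncorrected p threshold in (0, 1).
#' @param connectivity 6, 18 or 26.
#' @return Object of class `cluster_table`: data frame with one row per
#'   cluster (`cluster_id`, `size`, `peak_x/y/z` 1-based voxel indices,
#'   `peak_stat`), empty when nothing survives. Attribute `labels` maps
#'   suprathreshold voxels to cluster ids.
#' @export
form_clusters <- function(stat_map, cluster_forming_p = 0.001,
                          connectivity = 18) {
  if (cluster_forming_p <= 0 || cluster_forming_p >= 1)
    stop_config("cluster_forming_p must be in (0, 1)")
  supra <- which(stat_map$p < cluster_forming_p)
  empty <- data.frame(cluster_id = integer(0), size = integer(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0), peak_stat = numeric(0))
  if (!length(supra)) {
    return(structure(empty, labels = integer(0),
                     class = c("cluster_table", "data.frame")))
  }
  lin <- stat_map$voxel_index[supra]
  labs <- label_components(lin, stat_map$dim, connectivity)
  rows <- lapply(sort(unique(labs)), function(L) {
    members <- which(labs == L)
    w <- stat_map$wald[supra[members]]
    pk <- members[order(-w, lin[members])[1]]
    coord <- arrayInd(lin[pk], stat_map$dim)
    data.frame(cluster_id = L, size = length(members),
               peak_x = coord[1], peak_y = coord[2], peak_z = coord[3],
               peak_stat = stat_map$wald[supra[pk]])
  })
  structure(do.call(rbind, rows),
            labels = stats::setNames(labs, lin),
            class = c("cluster_table", "data.frame"))
}
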