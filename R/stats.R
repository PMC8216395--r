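#' Summary statistics of a tissue state
#'
#' One row of the quantities tracked along a simulation: cell counts by
#' type, endothelial area fraction (endothelial polygon area over total
#' tissue area), lumen count and areas, the proliferating-fraction proxy
#' overall and by peripheral/central class, and the number of connected
#' epithelial components (islets of the fragmenting epithelial mass).
#'
#' @param mesh a [tissue_mesh()].
#' @param prolif a [proliferation_params()] (for the EdU-proxy window).
#' @return A one-row tibble. `lumen_area_mean` is 0 with
#'   `has_lumina = FALSE` when no lumen exists.
#' @export
compute_summary_stats <- function(mesh, prolif = proliferation_params()) {
  A <- cell_areas(mesh)
  ty <- mesh$type
  cnt <- table(factor(ty, levels = CELL_TYPES))
  endo <- is_endothelial(ty)
  lum <- ty == "lumen"
  pf <- proliferating_fraction(mesh, prolif)
  tibble::tibble(
    time = mesh$clock,
    n_cells = length(ty),
    n_epithelial_central = as.integer(cnt[["epithelial_central"]]),
    n_epithelial_peripheral = as.integer(cnt[["epithelial_peripheral"]]),
    n_endothelial_tip = as.integer(cnt[["endothelial_tip"]]),
    n_endothelial_stalk = as.integer(cnt[["endothelial_stalk"]]),
    lumen_count = as.integer(cnt[["lumen"]]),
    endothelial_fraction = sum(A[endo]) / sum(A),
    lumen_area_total = sum(A[lum]),
    lumen_area_mean = if (any(lum)) mean(A[lum]) else 0,
    has_lumina = any(lum),
    prolif_fraction = pf[["overall"]],
    prolif_fraction_peripheral = pf[["peripheral"]],
    prolif_fraction_central = pf[["central"]],
    islet_count = count_epithelial_islets(mesh)
  )
}

#' Number of connected epithelial components (islets)
#'
#' Connected components of the epithelial cell-adjacency graph: the
#' fragments into which endothelial invasion splits the initial mass.
#'
#' @param mesh a [tissue_mesh()].
#' @return Integer count (0 when no epithelial cell remains).
#' @export
count_epithelial_islets <- function(mesh) {
  ep <- which(is_epithelial(mesh$type))
  if (!length(ep)) return(0L)
  adj <- adj_struct(mesh)
  keep <- adj$a %in% ep & adj$b %in% ep
  a <- match(adj$a[keep], ep); b <- match(adj$b[keep], ep)
  # union-find
  parent <- seq_along(ep)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_along(ep), find, integer(1))))
}
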