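#' Default junctional-rearrangement thresholds
#'
#' Lengths in cell-diameter units: edges shorter than `t1` trigger a T1
#' swap and are recreated at `t1_new_frac * t1`; triangles smaller than
#' `t2` are removed; boundary vertices within `t3_tol` of a facing
#' boundary edge are merged into it. `max_iter` caps one sweep.
#'
#' @param t1 T1 edge-length threshold.
#' @param t1_new_frac post-T1 edge length as a multiple of `t1`.
#' @param t2 T2 area threshold.
#' @param t3_tol T3 vertex--edge merge tolerance.
#' @param max_iter iteration cap per [rearrangement_sweep()].
#' @return list of thresholds.
#' @export
rearrangement_thresholds <- function(t1 = 0.01, t1_new_frac = 1.5,
                                     t2 = 0.001, t3_tol = 0.005,
                                     max_iter = 100L) {
  list(t1 = t1, t1_new_frac = t1_new_frac, t2 = t2, t3_tol = t3_tol,
       max_iter = as.integer(max_iter))
}

cells_containing <- function(mesh, v) {
  as.integer(cells_containing_cpp(mesh$cells, as.integer(v)))
}

# Insert vertex `new` into `ring` adjacent to `anchor`, choosing the side
# that yields a simple CCW polygon. Returns NULL if neither works.
insert_adjacent <- function(pos, ring, anchor, new) {
  i <- match(anchor, ring)
  cand <- list(append(ring, new, after = i),
               append(ring, new, after = i - 1L))
  for (r in cand) {
    if (ring_signed_area(pos, r) > 0 && ring_is_simple(pos, r)) return(r)
  }
  NULL
}

ring_remove <- function(ring, v) ring[ring != v]

#' T1 swap (edge rearrangement)
#'
#' Reconnects a too-short edge: the two cells sharing it become
#' non-adjacent and the two flanking cells gain a shared edge, recreated
#' perpendicular to the old one at length `t1_new_frac * t1`. Boundary
#' variants (edge on the tissue boundary, or an endpoint of cell-degree 2)
#' are handled without crashing: a boundary edge is collapsed to its
#' midpoint, and a missing flanking cell is treated as the outside. Edges
#' whose two endpoints are both fixed are exempt (they sit on endothelial
#' anchors).
#'
#' @param mesh a [tissue_mesh()].
#' @param edge integer pair `c(v1, v2)`.
#' @param thresholds see [rearrangement_thresholds()].
#' @return The updated mesh; unchanged (with attribute `t1_failed`) when
#'   the swap is topologically impossible here.
#' @export
apply_t1 <- function(mesh, edge, thresholds = rearrangement_thresholds()) {
  a <- edge[1]; b <- edge[2]
  L <- sqrt(sum((mesh$pos[a, ] - mesh$pos[b, ])^2))
  if (L >= thresholds$t1) return(mesh)            # no-op: not short
  mid0 <- (mesh$pos[a, ] + mesh$pos[b, ]) / 2
  # failures also register a (short) cooldown so hopeless sites are
  # rejected instantly instead of re-analysed every sweep
  failed <- function(m) {
    m$split_cooldown <- rbind(m$split_cooldown, c(mid0, m$clock + 0.05))
    attr(m, "t1_failed") <- TRUE
    m
  }
  if (mesh$fixed[a] && mesh$fixed[b]) return(failed(mesh))
  # hysteresis: a swap that just happened here would only oscillate back;
  # refuse further T1 activity at this site until the cooldown expires
  cd <- mesh$split_cooldown
  if (!is.null(cd) && nrow(cd)) {
    d2 <- (cd[, 1] - mid0[1])^2 + (cd[, 2] - mid0[2])^2
    if (any(d2 < 0.03^2 & cd[, 3] > mesh$clock)) {
      attr(mesh, "t1_failed") <- TRUE
      return(mesh)
    }
  }

  ca <- cells_containing(mesh, a)
  cb <- cells_containing(mesh, b)
  P <- intersect(ca, cb)        # cells sharing the edge
  R <- setdiff(ca, cb)          # flank at a
  S <- setdiff(cb, ca)          # flank at b

  if (length(P) == 1 && length(R) >= 1 && length(S) >= 1) {
    # boundary edge: collapse to midpoint (merges a and b)
    return(collapse_edge(mesh, a, b))
  }
  if (length(P) == 2 && length(R) == 0 && length(S) == 0) {
    # double edge: the two cells share both edges at this vertex pair;
    # swapping is meaningless, merge the endpoints instead
    return(collapse_edge(mesh, a, b))
  }
  if (length(P) != 2) return(failed(mesh))
  if (length(R) > 1 || length(S) > 1) return(failed(mesh))  # rosette-adjacent; skip
  # cells losing a vertex must keep >= 3
  if (any(lengths(mesh$cells[P]) < 4)) return(failed(mesh))

  old <- mesh
  m <- colMeans(mesh$pos[c(a, b), , drop = FALSE])
  u <- (mesh$pos[b, ] - mesh$pos[a, ]); u <- u / sqrt(sum(u^2))
  w <- c(-u[2], u[1])
  lnew <- thresholds$t1_new_frac * thresholds$t1
  cenP <- ring_centroid(mesh$pos, mesh$cells[[P[1]]])
  if (sum(w * (cenP - m)) < 0) w <- -w
  pa <- m + (lnew / 2) * w   # a stays with P[1]
  pb <- m - (lnew / 2) * w
  if (!mesh$fixed[a]) mesh$pos[a, ] <- pa
  if (!mesh$fixed[b]) mesh$pos[b, ] <- pb

  mesh$cells[[P[1]]] <- ring_remove(mesh$cells[[P[1]]], b)
  mesh$cells[[P[2]]] <- ring_remove(mesh$cells[[P[2]]], a)
  ok <- TRUE
  if (length(R) == 1) {
    r <- insert_adjacent(mesh$pos, mesh$cells[[R]], a, b)
    if (is.null(r)) ok <- FALSE else mesh$cells[[R]] <- r
  }
  if (ok && length(S) == 1) {
    r <- insert_adjacent(mesh$pos, mesh$cells[[S]], b, a)
    if (is.null(r)) ok <- FALSE else mesh$cells[[S]] <- r
  }
  if (ok) {
    aff <- c(P, R, S)
    ok <- all(vapply(aff, function(i) {
      rg <- mesh$cells[[i]]
      length(rg) >= 3 && ring_signed_area(mesh$pos, rg) > 0 &&
        ring_is_simple(mesh$pos, rg)
    }, logical(1)))
  }
  if (ok) ok <- tryCatch({ edge_struct(mesh); TRUE }, error = function(e) FALSE)
  if (!ok) return(failed(old))
  mesh$split_cooldown <- rbind(mesh$split_cooldown, c(mid0, mesh$clock + 0.2))
  # boundary variants (missing flank cells) can leave degree-2 interior
  # vertices; track them for the rosette pass
  track_violations(mesh)
}

# Collapse edge a-b into vertex a at the midpoint (boundary T1 variant).
collapse_edge <- function(mesh, a, b) {
  mid0 <- (mesh$pos[a, ] + mesh$pos[b, ]) / 2
  failed <- function(m) {
    m$split_cooldown <- rbind(m$split_cooldown, c(mid0, m$clock + 0.05))
    attr(m, "t1_failed") <- TRUE
    m
  }
  old <- mesh
  # cells containing b and a would lose distinctness
  affected <- cells_containing(mesh, b)
  for (i in affected) {
    r <- mesh$cells[[i]]
    r[r == b] <- a
    r <- r[c(TRUE, r[-1] != r[-length(r)])]
    if (r[1] == r[length(r)]) r <- r[-length(r)]
    if (anyDuplicated(r)) r <- repair_pinched_ring(r, mesh$pos)
    if (length(unique(r)) < 3) return(failed(old))
    mesh$cells[[i]] <- r
  }
  if (!mesh$fixed[a] && !mesh$fixed[b]) {
    mesh$pos[a, ] <- colMeans(mesh$pos[c(a, b), , drop = FALSE])
  } else if (mesh$fixed[b]) {
    mesh$pos[a, ] <- mesh$pos[b, ]
    mesh$fixed[a] <- TRUE
  }
  # geometric validation of every rewired cell; revert when the collapse
  # would flip or self-intersect a polygon, or leave an edge bordered by
  # more than two cells
  check <- union(affected, cells_containing(mesh, a))
  ok <- all(vapply(check, function(i) {
    rg <- mesh$cells[[i]]
    ring_signed_area(mesh$pos, rg) > 0 && ring_is_simple(mesh$pos, rg)
  }, logical(1)))
  if (ok) ok <- tryCatch({ edge_struct(mesh); TRUE }, error = function(e) FALSE)
  if (!ok) return(failed(old))
  # the merge can transiently break degree bounds (for the merged vertex
  # or its former neighbours); track everything for rosette resolution
  mesh$rosettes <- union(mesh$rosettes, a)
  mesh$split_cooldown <- rbind(mesh$split_cooldown,
                               c(mesh$pos[a, ], mesh$clock + 0.2))
  mesh <- compact_vertices(mesh)
  track_violations(mesh)
}

# A ring visiting a vertex twice is pinched into a figure-eight; keep the
# lobe with the larger area (the other is a degenerate sliver left by
# vertex merges) until no duplicates remain.
repair_pinched_ring <- function(ring, pos) {
  safe_area <- function(r) if (length(r) < 3) 0 else abs(ring_signed_area(pos, r))
  while (anyDuplicated(ring)) {
    v <- ring[anyDuplicated(ring)]
    idx <- which(ring == v)[1:2]
    n <- length(ring)
    sub1 <- ring[idx[1]:(idx[2] - 1L)]
    sub2 <- ring[c(idx[2]:n, seq_len(idx[1] - 1L))]
    ring <- if (safe_area(sub1) >= safe_area(sub2)) sub1 else sub2
  }
  ring
}

ring_centroid <- function(pos, ring) {
  x <- pos[ring, 1]; y <- pos[ring, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- 0.5 * sum(cr)
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * A)
}

#' T2 swap (small-triangle removal)
#'
#' Removes a triangular cell whose area has fallen below the threshold,
#' replacing it by a single vertex at its centroid (cell extrusion /
#' delamination). Lumen cells are exempt: follicular cavities persist.
#'
#' @param mesh a [tissue_mesh()].
#' @param cell index of the triangle.
#' @param area_threshold removal threshold (area units).
#' @return The updated mesh (cell count reduced by one), or the input mesh
#'   when the triangle is above threshold or is a lumen.
#' @export
apply_t2 <- function(mesh, cell, area_threshold = 0.001) {
  if (length(mesh$cells[[cell]]) != 3) stop("apply_t2 called on a non-triangle cell")
  if (mesh$type[cell] == "lumen") return(mesh)
  if (cell_area(mesh, cell) >= area_threshold) return(mesh)
  remove_cell_to_point(mesh, cell)
}

# Replace a (near-)degenerate cell of any vertex count by a single vertex
# at its centroid, re-wiring all neighbours (the T2 surgery, also used to
# clean up cells collapsed flat by the surrounding mechanics).
remove_cell_to_point <- function(mesh, cell) {
  orig <- mesh
  ring <- mesh$cells[[cell]]
  ctr <- ring_centroid(mesh$pos, ring)
  if (!all(is.finite(ctr))) ctr <- colMeans(mesh$pos[ring, , drop = FALSE])
  fx <- mesh$fixed[ring]
  res <- append_vertices(mesh, ctr, fixed = any(fx))
  mesh0 <- res$mesh; vnew <- res$ids
  if (any(fx)) mesh0$pos[vnew, ] <- mesh0$pos[ring[which(fx)[1]], ]
  # neighbours squeezed below three vertices by the re-wiring are
  # themselves degenerate and collapse onto the same point (cascade)
  to_point <- ring
  drop <- cell
  for (pass in 1:10) {
    mesh <- mesh0
    for (i in seq_along(mesh$cells)) {
      if (i %in% drop) next
      r <- mesh$cells[[i]]
      if (!any(r %in% to_point)) next
      r[r %in% to_point] <- vnew
      r <- r[c(TRUE, r[-1] != r[-length(r)])]
      if (r[1] == r[length(r)]) r <- r[-length(r)]
      if (anyDuplicated(r)) r <- repair_pinched_ring(r, mesh$pos)
      mesh$cells[[i]] <- r
    }
    bad <- setdiff(which(lengths(mesh$cells) < 3), drop)
    if (!length(bad)) break
    drop <- c(drop, bad)
    to_point <- union(to_point,
                      unlist(mesh0$cells[bad], use.names = FALSE))
  }
  failed <- function(m) { attr(m, "t2_failed") <- TRUE; m }
  if (length(setdiff(which(lengths(mesh$cells) < 3), drop)))
    return(failed(orig))
  mesh <- drop_cells(mesh, drop)
  mesh <- compact_vertices(mesh)
  ok <- tryCatch({ edge_struct(mesh); TRUE }, error = function(e) FALSE)
  if (!ok) return(failed(orig))
  # at the tissue edge the replacement vertex (or a re-wired neighbour
  # vertex) can exceed the degree bound; track for rosette resolution
  track_violations(mesh)
}


point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  proj <- a + t * ab
  list(d = sqrt(sum((p - proj)^2)), t = t, proj = proj)
}

#' T3 swap (boundary vertex--edge merge)
#'
#' When a boundary vertex of one cell approaches a boundary edge of a
#' non-incident cell within tolerance, the vertex is snapped onto the edge
#' and inserted into the facing cell's ring, merging the local boundaries
#' so the cells cannot interpenetrate. Interior collisions are not merged:
#' they signal an invariant violation.
#'
#' @param mesh a [tissue_mesh()].
#' @param vertex index of the approaching boundary vertex.
#' @param edge integer pair `c(v1, v2)` of the facing boundary edge.
#' @param tol merge tolerance (default from [rearrangement_thresholds()]).
#' @return The updated mesh (no-op when the vertex is farther than `tol`).
#' @export
apply_t3 <- function(mesh, vertex, edge, tol = 0.005) {
  bnd <- boundary_vertices(mesh)
  if (!bnd[vertex]) stop("T3 requested for an interior vertex: invariant violation")
  ed <- edge_struct(mesh)
  row <- which((ed$v1 == min(edge) & ed$v2 == max(edge)))
  if (!length(row) || !ed$boundary[row])
    stop("T3 requested for a non-boundary edge: invariant violation")
  owner <- ed$cell1[row]
  if (vertex %in% mesh$cells[[owner]]) return(mesh)  # already incident
  ps <- point_segment_distance(mesh$pos[vertex, ], mesh$pos[edge[1], ],
                               mesh$pos[edge[2], ])
  if (ps$d > tol) return(mesh)                       # no-op: not close enough
  if (!mesh$fixed[vertex]) mesh$pos[vertex, ] <- ps$proj
  old_mesh <- mesh
  ring <- mesh$cells[[owner]]
  n <- length(ring)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    if ((ring[i] == edge[1] && ring[j] == edge[2]) ||
        (ring[i] == edge[2] && ring[j] == edge[1])) {
      mesh$cells[[owner]] <- append(ring, vertex, after = i)
      break
    }
  }
  # refuse a merge that would give some edge more than two cells (the
  # vertex was already edge-adjacent to an endpoint through another cell)
  ok <- tryCatch({ edge_struct(mesh); TRUE }, error = function(e) FALSE)
  if (!ok) return(cool_site(old_mesh, old_mesh$pos[vertex, ], 0.2))
  # the merge may close the gap completely, stranding redundant interior
  # subdivision vertices; track every degree violation for the next
  # rosette-resolution pass
  track_violations(mesh)
}

# Site cooldown helpers: positions where an operation recently failed
# (or fired) are left alone until the expiry time, preventing churn.
site_cooled <- function(mesh, p, radius = 0.03) {
  cd <- mesh$split_cooldown
  if (is.null(cd) || !nrow(cd)) return(FALSE)
  any((cd[, 1] - p[1])^2 + (cd[, 2] - p[2])^2 < radius^2 &
        cd[, 3] > mesh$clock)
}

cool_site <- function(mesh, p, delay = 0.1) {
  mesh$split_cooldown <- rbind(mesh$split_cooldown, c(p[1], p[2], mesh$clock + delay))
  mesh
}

# Add every vertex violating the degree invariant to the tracked set
# (interior: exactly 3 cells; boundary: 1-2 cells).
track_violations <- function(mesh) {
  deg <- vertex_cell_degree(mesh)
  bnd <- boundary_vertices(mesh)
  viol <- which((!bnd & deg > 0 & deg != 3) | (bnd & deg > 2))
  mesh$rosettes <- union(mesh$rosettes, viol)
  mesh
}

# Remove an interior subdivision point: a vertex shared by exactly two
# cells with identical ring neighbours. Returns NULL when not applicable.
dissolve_redundant_vertex <- function(mesh, v) {
  own <- cells_containing(mesh, v)
  if (length(own) != 2) return(NULL)
  nbrs <- lapply(own, function(i) {
    r <- mesh$cells[[i]]; k <- match(v, r); n <- length(r)
    sort(c(r[k %% n + 1L], r[(k + n - 2L) %% n + 1L]))
  })
  if (!identical(nbrs[[1]], nbrs[[2]])) return(NULL)
  if (!all(lengths(mesh$cells[own]) > 3)) return(NULL)
  for (i in own) mesh$cells[[i]] <- ring_remove(mesh$cells[[i]], v)
  # the merged edge may already exist through a third cell
  ok <- tryCatch({ edge_struct(mesh); TRUE }, error = function(e) FALSE)
  if (!ok) return(NULL)
  compact_vertices(mesh)
}

#' Resolve multicellular rosettes
#'
#' A rosette is an interior vertex shared by more than three cells (or a
#' boundary vertex by more than two); they arise transiently during T1
#' cascades and after T3 merges. The vertex is split into two vertices
#' pulled apart along the direction of the two widest angular gaps
#' between incident-cell centroids; the two cells spanning the gaps gain
#' the new edge.
#'
#' @param mesh a [tissue_mesh()].
#' @param thresholds see [rearrangement_thresholds()] (sets the new edge
#'   length).
#' @return The updated mesh with `mesh$rosettes` pruned of resolved
#'   vertices.
#' @export
resolve_rosettes <- function(mesh, thresholds = rearrangement_thresholds()) {
  cd <- mesh$split_cooldown
  if (!is.null(cd) && nrow(cd))
    mesh$split_cooldown <- cd[cd[, 3] > mesh$clock, , drop = FALSE]
  repeat {
    mesh$rosettes <- integer(0)
    mesh <- track_violations(mesh)
    ros <- sort(mesh$rosettes)
    if (!length(ros)) break
    progress <- FALSE
    deg <- vertex_cell_degree(mesh)
    bnd <- boundary_vertices(mesh)
    for (v in ros) {
      if (site_cooled(mesh, mesh$pos[v, ])) next
      if (!bnd[v] && deg[v] == 2) {
        res <- dissolve_redundant_vertex(mesh, v)   # remaps vertex ids
        if (!is.null(res)) { mesh <- res; progress <- TRUE; break }
        mesh <- cool_site(mesh, mesh$pos[v, ], 0.1)
      } else if (deg[v] > 3 || (bnd[v] && deg[v] > 2)) {
        res <- split_rosette(mesh, v, thresholds)
        if (!is.null(res)) { mesh <- res; progress <- TRUE; break }
        mesh <- cool_site(mesh, mesh$pos[v, ], 0.1)
      }
    }
    if (!progress) break
  }
  mesh
}

# Split a high-degree vertex: one incident cell X (the most angularly
# isolated) is moved onto a new vertex v1 displaced toward X; X's angular
# neighbours gain the short edge v-v1 (a reverse T1). Degree drops by one;
# repeated application resolves any rosette. Returns NULL when no valid
# split exists (the rosette stays tracked).
split_rosette <- function(mesh, v, thresholds) {
  # an unstable split is immediately re-collapsed by the mechanics; after
  # a split near this position, leave the (tracked, valid) rosette alone
  # for a while instead of churning
  cd <- mesh$split_cooldown
  if (!is.null(cd) && nrow(cd)) {
    d2 <- (cd[, 1] - mesh$pos[v, 1])^2 + (cd[, 2] - mesh$pos[v, 2])^2
    if (any(d2 < 0.05^2 & cd[, 3] > mesh$clock)) return(NULL)
  }
  cells <- cells_containing(mesh, v)
  d <- length(cells)
  if (d < 3) return(NULL)
  cen <- t(vapply(cells, function(i) ring_centroid(mesh$pos, mesh$cells[[i]]),
                  numeric(2)))
  ang <- atan2(cen[, 2] - mesh$pos[v, 2], cen[, 1] - mesh$pos[v, 1])
  o <- order(ang)
  cells <- cells[o]; cen <- cen[o, , drop = FALSE]; ang <- ang[o]
  gaps <- c(diff(ang), ang[1] + 2 * pi - ang[d])   # gap after position i
  gap_before <- gaps[c(d, seq_len(d - 1))]
  isolation <- gap_before + gaps
  is_bnd <- boundary_vertices(mesh)[v]
  outside_gap <- if (is_bnd) which.max(gaps) else 0L
  ord <- order(-isolation, cells)                  # deterministic candidates
  delta <- thresholds$t1_new_frac * thresholds$t1  # above the T1 trigger
  for (xi in ord) {
    X <- cells[xi]
    prv <- if (xi == 1) d else xi - 1L
    nxt <- if (xi == d) 1L else xi + 1L
    # neighbours gaining the new edge; skip across the outside gap
    span <- integer(0)
    if (!(is_bnd && (prv == outside_gap) )) span <- c(span, cells[prv])
    if (!(is_bnd && (xi == outside_gap))) span <- c(span, cells[nxt])
    span <- setdiff(unique(span), X)
    dir1 <- cen[xi, ] - mesh$pos[v, ]
    n1 <- sqrt(sum(dir1^2)); if (n1 == 0) next
    dir1 <- dir1 / n1
    old <- mesh
    res <- append_vertices(mesh, rbind(mesh$pos[v, ] + delta * dir1),
                           fixed = FALSE)
    m2 <- res$mesh; v1 <- res$ids
    r <- m2$cells[[X]]
    r[r == v] <- v1
    m2$cells[[X]] <- r
    ok <- TRUE
    for (i in span) {
      r2 <- insert_adjacent(m2$pos, m2$cells[[i]], v, v1)
      if (is.null(r2)) { ok <- FALSE; break }
      m2$cells[[i]] <- r2
    }
    if (ok) {
      aff <- c(X, span)
      ok <- all(vapply(aff, function(i) {
        rg <- m2$cells[[i]]
        length(unique(rg)) >= 3 && ring_signed_area(m2$pos, rg) > 0 &&
          ring_is_simple(m2$pos, rg)
      }, logical(1)))
    }
    if (ok) ok <- tryCatch({ edge_struct(m2); TRUE }, error = function(e) FALSE)
    if (ok) {
      m2$split_cooldown <- rbind(m2$split_cooldown,
                                 c(m2$pos[v, ], m2$clock + 0.5))
      return(m2)
    }
    mesh <- old
  }
  NULL
}

#' Sweep all junctional rearrangements until quiescent
#'
#' Applies T2 removals, T1 swaps, rosette resolutions and T3 merges in a
#' fixed deterministic order (ascending cell / edge indices) until no
#' trigger remains or the iteration cap is hit. Restores the topology
#' invariants the dynamics rely on.
#'
#' @param mesh a [tissue_mesh()].
#' @param thresholds see [rearrangement_thresholds()].
#' @param on_cap `"error"` aborts with a diagnostic when the cap is hit;
#'   `"warn"` emits a warning and returns the current mesh.
#' @return The rearranged mesh.
#' @export
rearrangement_sweep <- function(mesh, thresholds = rearrangement_thresholds(),
                                on_cap = c("error", "warn")) {
  on_cap <- match.arg(on_cap)
  total_ops <- 0L
  capped <- FALSE
  bump <- function() {
    total_ops <<- total_ops + 1L
    if (total_ops > thresholds$max_iter) capped <<- TRUE
    capped
  }
  skip_t1 <- numeric(0)
  skip_t2 <- integer(0)
  repeat {
    acted <- FALSE
    # T2 phase: degenerate cells, ascending id; failures are skipped
    # without recomputation, successes invalidate indices and restart
    repeat {
      areas <- cell_areas(mesh)
      tiny <- setdiff(which(areas < thresholds$t2 & mesh$type != "lumen"),
                      skip_t2)
      success <- FALSE
      for (cell in tiny) {
        ctr <- colMeans(mesh$pos[mesh$cells[[cell]], , drop = FALSE])
        if (site_cooled(mesh, ctr)) { skip_t2 <- c(skip_t2, cell); next }
        m2 <- tryCatch({
          if (length(mesh$cells[[cell]]) == 3)
            apply_t2(mesh, cell, thresholds$t2)
          else remove_cell_to_point(mesh, cell)
        }, error = function(e) NULL)
        if (is.null(m2) || isTRUE(attr(m2, "t2_failed")) ||
            identical(m2$cells, mesh$cells)) {
          skip_t2 <- c(skip_t2, cell)
          mesh <- cool_site(mesh, ctr, 0.1)
        } else {
          attr(m2, "t2_failed") <- NULL
          mesh <- m2
          skip_t2 <- integer(0)   # ids shifted
          skip_t1 <- numeric(0)
          success <- TRUE; acted <- TRUE
          break
        }
      }
      if (!success || bump()) break
    }
    if (capped) break
    # T1 phase: short edges, ascending (v1, v2)
    repeat {
      ed <- edge_struct(mesh)
      short <- which(ed$length < thresholds$t1)
      if (length(short)) {
        keys <- edge_key(ed$v1[short], ed$v2[short])
        short <- short[!(keys %in% skip_t1)]
        short <- short[order(ed$v1[short], ed$v2[short])]
      }
      success <- FALSE
      for (i in short) {
        nv0 <- n_vertices(mesh)
        m2 <- apply_t1(mesh, c(ed$v1[i], ed$v2[i]), thresholds)
        if (isTRUE(attr(m2, "t1_failed"))) {
          skip_t1 <- c(skip_t1, edge_key(ed$v1[i], ed$v2[i]))
          mesh$split_cooldown <- m2$split_cooldown
        } else {
          attr(m2, "t1_failed") <- NULL
          mesh <- m2
          if (n_vertices(mesh) != nv0) skip_t1 <- numeric(0)  # ids remapped
          success <- TRUE; acted <- TRUE
          break
        }
      }
      if (!success || bump()) break
    }
    if (capped) break
    # rosette resolution (internally iterates to quiescence)
    deg <- vertex_cell_degree(mesh); bnd <- boundary_vertices(mesh)
    if (any((!bnd & deg > 0 & deg != 3) | (bnd & deg > 2))) {
      n_ros <- length(mesh$rosettes)
      mesh <- resolve_rosettes(mesh, thresholds)
      if (length(mesh$rosettes) < n_ros) acted <- TRUE
    } else {
      mesh$rosettes <- integer(0)
    }
    # T3 merges
    repeat {
      hit <- find_t3_candidate(mesh, thresholds$t3_tol)
      if (is.null(hit)) break
      m2 <- apply_t3(mesh, hit$vertex, hit$edge, thresholds$t3_tol)
      if (identical(m2$cells, mesh$cells) &&
          identical(m2$pos, mesh$pos)) break
      mesh <- m2
      acted <- TRUE
      if (bump()) break
    }
    if (!acted || capped) break
  }
  if (capped) {
    msg <- paste0("rearrangement_sweep: operation cap reached at t = ",
                  mesh$clock, " (", length(mesh$cells), " cells)")
    if (on_cap == "error") stop(msg)
    warning(msg)
  }
  mesh
}

# First boundary vertex lying within tol of a non-incident boundary edge
# (deterministic order: ascending vertex, then edge).
find_t3_candidate <- function(mesh, tol) {
  ed <- edge_struct(mesh)
  bi <- which(ed$boundary)
  if (!length(bi)) return(NULL)
  bv <- which(boundary_vertices(mesh))
  if (!length(bv)) return(NULL)
  cd <- mesh$split_cooldown
  if (!is.null(cd) && nrow(cd)) {
    cd <- cd[cd[, 3] > mesh$clock, , drop = FALSE]
    if (nrow(cd)) {
      cooled <- vapply(bv, function(v)
        any((cd[, 1] - mesh$pos[v, 1])^2 +
              (cd[, 2] - mesh$pos[v, 2])^2 < 0.03^2), logical(1))
      bv <- bv[!cooled]
      if (!length(bv)) return(NULL)
    }
  }
  a <- mesh$pos[ed$v1[bi], , drop = FALSE]
  b <- mesh$pos[ed$v2[bi], , drop = FALSE]
  mid <- (a + b) / 2
  reach <- ed$length[bi] / 2 + tol
  P <- mesh$pos[bv, , drop = FALSE]
  D2 <- outer(P[, 1], mid[, 1], "-")^2 + outer(P[, 2], mid[, 2], "-")^2
  cand <- which(D2 <= matrix(reach^2, length(bv), length(bi), byrow = TRUE),
                arr.ind = TRUE)
  if (!nrow(cand)) return(NULL)
  # drop pairs where the vertex is an endpoint of the edge
  keep <- bv[cand[, 1]] != ed$v1[bi[cand[, 2]]] &
    bv[cand[, 1]] != ed$v2[bi[cand[, 2]]]
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    v <- bv[cand[r, 1]]; k <- cand[r, 2]
    if (v %in% mesh$cells[[ed$cell1[bi[k]]]]) next
    ps <- point_segment_distance(mesh$pos[v, ], a[k, ], b[k, ])
    if (ps$d < tol && ps$t > 1e-9 && ps$t < 1 - 1e-9)
      return(list(vertex = v, edge = c(ed$v1[bi[k]], ed$v2[bi[k]])))
  }
  NULL
}

# Cool the site of a cell whose removal failed (run-loop helper).
thyromorph_cool_cell <- function(mesh, cell) {
  ctr <- colMeans(mesh$pos[mesh$cells[[cell]], , drop = FALSE])
  cool_site(mesh, ctr, 0.1)
}
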