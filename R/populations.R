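#' Proliferation parameters of the epithelial populations
#'
#' Cycle durations derived from EdU labelling at E13.5/E15.5: 11 h 20 min
#' for peripheral cells and 31 h 52 min for central cells. Each new
#' generation's cycle is multiplied by the generation factor `g >= 1`, so
#' proliferation slows as the tissue matures (the exponential decline of
#' the EdU-positive fraction). A lognormal jitter desynchronises sister
#' cells; the EdU proxy window marks cells within `edu_window` hours of
#' their next division as "S-phase" for reporting.
#'
#' @param T_peripheral,T_central baseline cycle durations (hours).
#' @param generation_factor multiplicative slow-down per generation.
#' @param jitter_sd fractional lognormal s.d. of cycle durations (0 = none).
#' @param edu_window EdU-proxy window (hours before division).
#' @return list of class `proliferation_params`.
#' @export
proliferation_params <- function(T_peripheral = 11 + 20 / 60,
                                 T_central = 31 + 52 / 60,
                                 generation_factor = 1.45,
                                 jitter_sd = 0.1,
                                 edu_window = 0.5) {
  stopifnot(T_peripheral > 0, T_central > 0, generation_factor >= 1,
            jitter_sd >= 0, edu_window >= 0)
  structure(list(T_peripheral = T_peripheral, T_central = T_central,
                 generation_factor = generation_factor,
                 jitter_sd = jitter_sd, edu_window = edu_window),
            class = "proliferation_params")
}

#' Endothelial population parameters
#'
#' @param elongation_threshold stalk cells divide when their
#'   [elongation_factor()] reaches this value (> 1).
#' @param branch_addition_rate Poisson rate (branches per hour) of new
#'   tip+stalk pairs appearing on the periphery.
#' @param branch_addition_cutoff no new branches after this time (hours);
#'   new tip cells appear only during the first 24 h.
#' @param branch_depth extrusion depth of newly added endothelial cells
#'   (cell-diameter units); kept small so added cells start thin.
#' @param division_min_area stalk cells must reach this area before a
#'   shape-triggered division (prevents runaway sliver divisions).
#' @param growth_time hours over which a newborn endothelial cell's
#'   target area regrows from half to full size.
#' @return list of class `endothelial_params`.
#' @export
endothelial_params <- function(elongation_threshold = 3,
                               branch_addition_rate = 1 / 6,
                               branch_addition_cutoff = 24,
                               branch_depth = 0.3,
                               division_min_area = 0.15,
                               growth_time = 9) {
  stopifnot(elongation_threshold > 1, branch_addition_rate >= 0,
            branch_addition_cutoff >= 0, branch_depth > 0,
            division_min_area >= 0, growth_time > 0)
  structure(list(elongation_threshold = elongation_threshold,
                 branch_addition_rate = branch_addition_rate,
                 branch_addition_cutoff = branch_addition_cutoff,
                 branch_depth = branch_depth,
                 division_min_area = division_min_area,
                 growth_time = growth_time),
            class = "endothelial_params")
}

#' Classify epithelial cells as peripheral or central
#'
#' A peripheral cell has at least one edge not shared with another cell
#' (an unshared, tissue-boundary edge); by default cells touching
#' endothelium also count as peripheral, since the in vivo periphery is
#' defined by ECM/vessel contact. Central cells share every edge with
#' other epithelial cells. Endothelial and lumen cells are untouched.
#' Re-run every step so the labels track the changing morphology.
#'
#' @param mesh a [tissue_mesh()].
#' @param endothelial_contact count contact with endothelial cells as
#'   peripheral (default TRUE).
#' @return The mesh with updated epithelial `type` labels.
#' @export
classify_peripherality <- function(mesh, endothelial_contact = TRUE) {
  ed <- edge_struct(mesh)
  peri <- rep(FALSE, n_cells(mesh))
  peri[ed$cell1[ed$boundary]] <- TRUE
  if (endothelial_contact) {
    ii <- which(!ed$boundary)
    endo1 <- is_endothelial(mesh$type[ed$cell1[ii]])
    endo2 <- is_endothelial(mesh$type[ed$cell2[ii]])
    peri[ed$cell1[ii][endo2]] <- TRUE
    peri[ed$cell2[ii][endo1]] <- TRUE
  }
  ep <- is_epithelial(mesh$type)
  mesh$type[ep & peri] <- "epithelial_peripheral"
  mesh$type[ep & !peri] <- "epithelial_central"
  mesh
}

#' Cycle duration for a newborn epithelial cell
#'
#' `T_type * g^generation`, optionally jittered by a lognormal factor of
#' fractional s.d. `jitter_sd` (draws from the current RNG stream).
#'
#' @param type `"epithelial_peripheral"` or `"epithelial_central"`.
#' @param generation integer generation number (founders are 0).
#' @param params a [proliferation_params()].
#' @param jitter apply the lognormal jitter (default TRUE; the no-jitter
#'   value is the deterministic baseline).
#' @return Duration in hours, strictly positive.
#' @export
cycle_duration_at_birth <- function(type, generation, params, jitter = TRUE) {
  if (!all(is_epithelial(type)))
    stop("cycle durations are defined for epithelial cells only")
  base <- ifelse(type == "epithelial_peripheral",
                 params$T_peripheral, params$T_central)
  dur <- base * params$generation_factor^generation
  if (jitter && params$jitter_sd > 0) {
    sdlog <- sqrt(log(1 + params$jitter_sd^2))
    dur <- dur * stats::rlnorm(length(dur), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  dur
}

#' Advance cell ages and perform cycle-driven epithelial divisions
#'
#' All ages advance by `dt`. Epithelial cells whose age has reached their
#' cycle duration divide along their shortest axis; daughters restart at
#' age 0, generation + 1, with freshly sampled durations. Tip cells are
#' differentiated and never divide; stalk cells divide by shape (see
#' [stalk_divide_if_elongated()]); lumen cells never proliferate. Cells
#' listed in `exclude` (e.g. pre-empted by a polarity-triggered lumen
#' division this step) are skipped.
#'
#' @param mesh a [tissue_mesh()].
#' @param params a [proliferation_params()].
#' @param dt elapsed time (hours).
#' @param exclude integer cell indices to skip this step.
#' @return `list(mesh, events)`; `events` is a tibble with one row per
#'   division (time, mother type, generation, daughter ids).
#' @export
advance_cycles_and_divide <- function(mesh, params, dt, exclude = integer(0)) {
  mesh$age <- mesh$age + dt
  due <- which(is_epithelial(mesh$type) & mesh$age >= mesh$cycle_duration)
  due <- setdiff(due, exclude)
  events <- list()
  for (cell in due) {
    div <- tryCatch(divide_cell(mesh, cell), error = function(e) NULL)
    if (is.null(div)) next                        # geometry refused; retry later
    mesh <- div$mesh
    gen <- mesh$generation[cell] + 1L
    for (d in div$daughters) {
      mesh$age[d] <- 0
      mesh$generation[d] <- gen
      mesh$cycle_duration[d] <-
        cycle_duration_at_birth(mesh$type[d], gen, params)
    }
    events[[length(events) + 1L]] <-
      tibble::tibble(time = mesh$clock, event = "division",
                     cell_type = mesh$type[cell], generation = gen,
                     cell = cell, daughter = div$daughters[2])
  }
  list(mesh = mesh, events = do.call(rbind, events))
}

#' Divide elongated stalk cells
#'
#' Stalk cells have no timed cycle: they divide by shape, when their
#' [elongation_factor()] reaches the threshold, filling the space opened
#' by tip-cell migration. Daughters are stalk cells; fixed-vertex
#' anchoring is preserved (division adds vertices, it never unfixes any).
#'
#' @param mesh a [tissue_mesh()].
#' @param params an [endothelial_params()].
#' @return `list(mesh, events)` as in [advance_cycles_and_divide()].
#' @export
stalk_divide_if_elongated <- function(mesh, params) {
  stalks <- which(mesh$type == "endothelial_stalk")
  events <- list()
  if (length(stalks)) areas <- cell_areas(mesh)
  for (cell in stalks) {
    if (areas[cell] < params$division_min_area) next
    ef <- tryCatch(elongation_factor(mesh, cell), error = function(e) 1)
    if (ef < params$elongation_threshold) next
    div <- tryCatch(divide_cell(mesh, cell), error = function(e) NULL)
    if (is.null(div)) next
    mesh <- div$mesh
    for (d in div$daughters) mesh$age[d] <- 0
    events[[length(events) + 1L]] <-
      tibble::tibble(time = mesh$clock, event = "stalk_division",
                     cell_type = "endothelial_stalk",
                     generation = mesh$generation[cell],
                     cell = cell, daughter = div$daughters[2])
  }
  list(mesh = mesh, events = do.call(rbind, events))
}

#' Proliferating-fraction proxy (in-silico EdU)
#'
#' Fraction of epithelial cells within `edu_window` hours of their next
#' division, overall and by peripheral/central class. A reporting proxy
#' for the EdU-positive fraction, not a biochemical S-phase model.
#'
#' @param mesh a [tissue_mesh()].
#' @param params a [proliferation_params()].
#' @return Named numeric vector `overall`, `peripheral`, `central` (NA for
#'   an empty class).
#' @export
proliferating_fraction <- function(mesh, params) {
  ep <- is_epithelial(mesh$type)
  marked <- ep & (mesh$cycle_duration - mesh$age) <= params$edu_window &
    is.finite(mesh$cycle_duration)
  frac <- function(sel) if (any(sel)) mean(marked[sel]) else NA_real_
  c(overall = frac(ep),
    peripheral = frac(mesh$type == "epithelial_peripheral"),
    central = frac(mesh$type == "epithelial_central"))
}

#' Add a new endothelial branch at the periphery
#'
#' Inserts one differentiated tip cell and one stalk cell on the tissue
#' periphery, at the epithelial boundary edge farthest from any existing
#' endothelial cell (the largest unoccupied gap). The pair is extruded
#' outward from that edge as two thin quadrilaterals (stalk outermost), a
#' corridor is registered at the stalk ([register_endo_boundary()]) and
#' the stalk's outer vertices are fixed. Mimics endothelial cells
#' arriving from vessels outside the imaged section; no-op after the
#' addition cutoff (new tip cells appear only during the first 24 h).
#'
#' @param mesh a [tissue_mesh()].
#' @param params an [endothelial_params()].
#' @param clock current simulation time (default the mesh clock).
#' @param endo_A0 target area given to the new endothelial cells.
#' @return `list(mesh, added)`; `added` is TRUE when a branch was placed
#'   (FALSE past the cutoff or when no admissible site exists, with a
#'   warning in the latter case).
#' @export
add_endothelial_branch <- function(mesh, params, clock = mesh$clock,
                                   endo_A0 = 0.3) {
  if (clock >= params$branch_addition_cutoff)
    return(list(mesh = mesh, added = FALSE))
  ed <- edge_struct(mesh)
  ci <- which(ed$boundary & is_epithelial(mesh$type[ed$cell1]) &
                ed$length >= 0.3)
  if (length(ci)) {
    ok <- !mesh$fixed[ed$v1[ci]] & !mesh$fixed[ed$v2[ci]]
    endo_touch <- vertex_touches(mesh, c("endothelial_tip", "endothelial_stalk"))
    ok <- ok & !endo_touch[ed$v1[ci]] & !endo_touch[ed$v2[ci]]
    ci <- ci[ok]
  }
  cand <- list(v1 = ed$v1[ci], v2 = ed$v2[ci], cell1 = ed$cell1[ci])
  if (!length(ci)) {
    warning("no admissible peripheral site for a new endothelial branch")
    return(list(mesh = mesh, added = FALSE))
  }
  mids <- (mesh$pos[cand$v1, , drop = FALSE] + mesh$pos[cand$v2, , drop = FALSE]) / 2
  endo <- which(is_endothelial(mesh$type))
  if (length(endo)) {
    ecen <- t(vapply(endo, function(i) ring_centroid(mesh$pos, mesh$cells[[i]]),
                     numeric(2)))
    dmin <- apply(mids, 1, function(m)
      min(sqrt((ecen[, 1] - m[1])^2 + (ecen[, 2] - m[2])^2)))
  } else {
    dmin <- rep(Inf, length(cand$v1))
  }
  pick <- which.max(dmin)
  host <- cand$cell1[pick]
  # orient (va -> vb) as the host's CCW half-edge so outward = right side
  ring <- mesh$cells[[host]]
  nring <- length(ring)
  va <- cand$v1[pick]; vb <- cand$v2[pick]
  for (i in seq_len(nring)) {
    if (ring[i] == vb && ring[i %% nring + 1L] == va) { tmp <- va; va <- vb; vb <- tmp }
  }
  d <- mesh$pos[vb, ] - mesh$pos[va, ]
  nout <- c(d[2], -d[1]); nout <- nout / sqrt(sum(nout^2))
  dep <- params$branch_depth
  res <- append_vertices(mesh, rbind(
    mesh$pos[va, ] + dep * nout, mesh$pos[vb, ] + dep * nout,       # tip outer
    mesh$pos[va, ] + 2 * dep * nout, mesh$pos[vb, ] + 2 * dep * nout))
  mesh <- res$mesh
  va1 <- res$ids[1]; vb1 <- res$ids[2]; va2 <- res$ids[3]; vb2 <- res$ids[4]
  rc <- append_cell(mesh, c(va, vb, vb1, va1), "endothelial_tip", A0 = endo_A0)
  mesh <- rc$mesh
  rc <- append_cell(mesh, c(va1, vb1, vb2, va2), "endothelial_stalk", A0 = endo_A0)
  mesh <- rc$mesh
  stalk_id <- rc$id
  # re-orient the new rings CCW (append_cell does not)
  for (id in c(stalk_id - 1L, stalk_id)) {
    if (ring_signed_area(mesh$pos, mesh$cells[[id]]) < 0)
      mesh$cells[[id]] <- rev(mesh$cells[[id]])
  }
  mesh <- register_endo_boundary(mesh, stalk_id)
  # the two junction vertices now border three cells while still on the
  # boundary; track them as rosettes for the next rearrangement sweep
  deg <- vertex_cell_degree(mesh)
  bnd <- boundary_vertices(mesh)
  mesh$rosettes <- union(mesh$rosettes, which((!bnd & deg > 3) | (bnd & deg > 2)))
  list(mesh = mesh, added = TRUE, tip = stalk_id - 1L, stalk = stalk_id)
}
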