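# Orchestration: the chunked fast path (compiled mechanical substeps with
# R-level topology/biology between chunks) and the single-step reference
# path used for verification.

type_codes <- function(mesh) match(mesh$type, CELL_TYPES) - 1L

# Flatten the mesh topology for the compiled core. skip_t1: edge keys the
# T1 operator refused (treated as exempt until the topology changes).
flatten_mesh <- function(mesh, eparams, thresholds, skip_t1 = numeric(0),
                         ed = edge_struct(mesh)) {
  rings <- mesh$cells
  lens <- lengths(rings)
  lam <- edge_lambda(mesh, eparams, ed)
  exempt <- (mesh$fixed[ed$v1] & mesh$fixed[ed$v2]) |
    (edge_key(ed$v1, ed$v2) %in% skip_t1)
  proj_ok <- vertex_touches(mesh, c("epithelial_central", "epithelial_peripheral")) &
    !vertex_touches(mesh, c("endothelial_tip", "endothelial_stalk", "lumen")) &
    !mesh$fixed
  # cells at cooled sites are exempt from the compiled small-cell trigger
  c_exempt <- rep(FALSE, length(mesh$cells))
  cd <- mesh$split_cooldown
  if (!is.null(cd) && nrow(cd)) {
    cd <- cd[cd[, 3] > mesh$clock, , drop = FALSE]
    if (nrow(cd)) {
      cp0 <- c(0L, cumsum(lens))
      g0 <- cell_geom_cpp(mesh$pos, cp0, unlist(rings, use.names = FALSE) - 1L)
      for (r in seq_len(nrow(cd))) {
        c_exempt <- c_exempt |
          ((g0$cx - cd[r, 1])^2 + (g0$cy - cd[r, 2])^2 < 0.03^2)
      }
    }
  }
  bcs <- Filter(function(b) b$active, mesh$boundaries)
  cmat <- if (length(bcs)) {
    do.call(rbind, lapply(bcs, function(b)
      c(b$anchor, b$direction, b$half_width)))
  } else {
    matrix(0, 0, 5)
  }
  list(cellptr = c(0L, cumsum(lens)),
       ring = unlist(rings, use.names = FALSE) - 1L,
       typecode = type_codes(mesh),
       ev1 = ed$v1 - 1L, ev2 = ed$v2 - 1L, elam = lam,
       exempt = exempt, c_exempt = c_exempt, proj_ok = proj_ok,
       corridors = cmat, edges = ed)
}

# Steady-state VEGF + per-vertex chemotactic forces for the current mesh
# (lean path: shared edge structure, gradients only at tip cells with the
# two-ring stencil).
chemo_forces <- function(mesh, config, ed = edge_struct(mesh)) {
  F <- matrix(0, n_vertices(mesh), 2)
  tips <- which(mesh$type == "endothelial_tip")
  if (!length(tips) || config$chemo$mu == 0) return(F)
  mp <- config$morphogen
  if (config$vegfa_ko) mp$s <- 0
  if (mp$s <= 0) return(F)
  nc <- n_cells(mesh)
  adj <- adj_struct(mesh, ed)
  cp <- c(0L, cumsum(lengths(mesh$cells)))
  g <- cell_geom_cpp(mesh$pos, cp, unlist(mesh$cells, use.names = FALSE) - 1L)
  cen <- cbind(g$cx, g$cy)
  A <- g$area
  dirichlet <- unique(ed$cell1[ed$boundary])
  conc <- solve_vegf_core(adj, cen, A, is_epithelial(mesh$type), mp,
                          dirichlet, nc, method = "cg")
  for (tip in tips) {
    nb1 <- c(adj$b[adj$a == tip], adj$a[adj$b == tip])
    nb2 <- unique(unlist(lapply(nb1, function(j)
      c(adj$b[adj$a == j], adj$a[adj$b == j]))))
    nb <- setdiff(unique(c(nb1, nb2)), tip)
    if (length(nb) < 2) next
    X <- cen[nb, , drop = FALSE] -
      matrix(cen[tip, ], length(nb), 2, byrow = TRUE)
    y <- conc[nb] - conc[tip]
    XtX <- crossprod(X)
    if (abs(det(XtX)) < 1e-12) next
    g <- solve(XtX, crossprod(X, y))
    gn <- sqrt(sum(g^2))
    if (gn < config$chemo$gradient_floor) next
    f <- config$chemo$mu * g / gn
    vs <- mesh$cells[[tip]]
    F[vs, 1] <- F[vs, 1] + f[1]
    F[vs, 2] <- F[vs, 2] + f[2]
  }
  F
}

# Instantaneous epithelial target areas: linear growth from half to full
# mature size over one cycle; endothelial and lumen targets are their
# reference values.
refresh_targets <- function(mesh, endo_growth_time = 6) {
  ep <- is_epithelial(mesh$type)
  endo <- is_endothelial(mesh$type)
  frac <- 0.5 + 0.5 * pmin(mesh$age / mesh$cycle_duration, 1)
  frac[!is.finite(frac)] <- 1
  efrac <- 0.5 + 0.5 * pmin(mesh$age / endo_growth_time, 1)
  mesh$A0 <- ifelse(ep, mesh$A0_ref * frac,
                    ifelse(endo, mesh$A0_ref * efrac, mesh$A0_ref))
  mesh
}

#' One full simulation step (reference path)
#'
#' Executes one `dt` step in the fixed order: morphogen solve +
#' chemotactic forces, polarity update, tissue forces, Euler update,
#' corridor enforcement, rearrangement sweep, lumen creation,
#' cycle-driven and shape-driven divisions, branch addition (caller's
#' responsibility via [simulate_tissue()]'s Poisson clock), and
#' reclassification. Slow but transparent; [simulate_tissue()] runs the
#' compiled equivalent in chunks.
#'
#' @param mesh a [tissue_mesh()].
#' @param config a [run_config()].
#' @return `list(mesh, events)`.
#' @export
step_tissue <- function(mesh, config) {
  dt <- config$dt
  mesh <- refresh_targets(mesh, config$endo$growth_time)
  addF <- if (config$chemotaxis) chemo_forces(mesh, config) else
    matrix(0, n_vertices(mesh), 2)
  if (config$polarity)
    mesh <- update_polarity(mesh, config$pol, dt, config$lumen)
  F <- vertex_forces(mesh, config$energy) + addF
  mesh <- euler_step(mesh, F, dt)
  mesh <- enforce_corridors(mesh)
  mesh <- rearrangement_sweep(mesh, config$thresholds, on_cap = "warn")
  events <- NULL
  excl <- integer(0)
  if (config$polarity) {
    mesh <- grow_lumina(mesh, config$lumen, dt)
    for (cell in check_polarised_division(mesh, config$pol)) {
      res <- create_lumen(mesh, cell, config$lumen)
      if (is.null(res)) next
      mesh <- res$mesh
      excl <- c(excl, res$lumen_id, res$epithelial_id)
      events <- rbind(events, tibble::tibble(
        time = mesh$clock, event = "lumen_created",
        cell_type = "lumen", generation = NA_integer_,
        cell = cell, daughter = res$lumen_id))
    }
  }
  if (config$proliferation) {
    res <- advance_cycles_and_divide(mesh, config$prolif, dt, exclude = excl)
    mesh <- res$mesh
    events <- rbind(events, res$events)
  } else {
    mesh$age <- mesh$age + dt
  }
  if (config$stalk_division) {
    res <- stalk_divide_if_elongated(mesh, config$endo)
    mesh <- res$mesh
    events <- rbind(events, res$events)
  }
  mesh <- classify_peripherality(mesh)
  list(mesh = mesh, events = events)
}

#' Run a full simulation
#'
#' Simulates thyroid morphogenesis from an initial condition (default:
#' [synthesize_e13_ic()] with the configured size) for the configured
#' duration: epithelial growth with differential peripheral/central
#' proliferation, VEGF-driven endothelial invasion under the endo-BC
#' corridors, junctional rearrangements, and (if enabled) polarisation
#' and follicular lumen formation. Mechanical substeps run in compiled
#' code; topology changes, the morphogen solve, polarity and biology run
#' every `macro_every` steps.
#'
#' @param config a [run_config()].
#' @param ic optional [tissue_mesh()] initial condition.
#' @param validate run the full invariant check after every topology
#'   event (slow; for debugging and tests).
#' @return list of class `tissue_run`: `mesh` (final state), `stats`
#'   (tibble, one row per sample time), `events` (tibble event log),
#'   `config`.
#' @export
simulate_tissue <- function(config = run_config(), ic = NULL,
                            validate = FALSE) {
  set.seed(config$seed)
  mesh <- if (is.null(ic)) {
    synthesize_e13_ic(config$n_epithelial, prolif = config$prolif,
                      endo_params = config$endo)
  } else {
    ic
  }
  mesh <- rearrangement_sweep(mesh, config$thresholds, on_cap = "warn")
  mesh <- classify_peripherality(mesh)
  dt <- config$dt
  n_steps <- round(config$duration / dt)
  stats_rows <- list(compute_summary_stats(mesh, config$prolif))
  events <- list()
  push_event <- function(ev) if (!is.null(ev)) events[[length(events) + 1L]] <<- ev
  next_branch <- if (config$branch_addition && config$endo$branch_addition_rate > 0)
    mesh$clock + stats::rexp(1, config$endo$branch_addition_rate) else Inf
  next_stats <- mesh$clock + config$stats_every
  skip_t1 <- numeric(0)
  step_i <- 0L
  addF <- NULL
  topo_dirty <- TRUE

  ed <- NULL
  last_skip_reset <- 0L
  while (step_i < n_steps) {
    chunk <- min(config$macro_every, n_steps - step_i)
    if (step_i - last_skip_reset >= 1000L) {     # re-attempt refused swaps hourly
      skip_t1 <- numeric(0)
      last_skip_reset <- step_i
    }
    mesh <- refresh_targets(mesh, config$endo$growth_time)
    if (is.null(ed)) {
      ed <- edge_struct(mesh)
    } else {
      ed$length <- sqrt((mesh$pos[ed$v1, 1] - mesh$pos[ed$v2, 1])^2 +
                          (mesh$pos[ed$v1, 2] - mesh$pos[ed$v2, 2])^2)
    }
    if (config$chemotaxis) {
      addF <- chemo_forces(mesh, config, ed)
    } else if (is.null(addF) || nrow(addF) != n_vertices(mesh)) {
      addF <- matrix(0, n_vertices(mesh), 2)
    }
    topo_changed <- FALSE
    needs_sweep <- FALSE
    # mechanical substeps with event-driven returns
    done <- 0L
    while (done < chunk) {
      if (is.null(ed)) ed <- edge_struct(mesh)
      fl <- flatten_mesh(mesh, config$energy, config$thresholds, skip_t1, ed)
      out <- vm_advance_cpp(mesh$pos, mesh$fixed, fl$cellptr, fl$ring,
                            fl$typecode, mesh$A0, config$energy$K,
                            config$energy$gamma, fl$ev1, fl$ev2, fl$elam,
                            fl$exempt, fl$c_exempt, addF, fl$corridors,
                            fl$proj_ok, dt, chunk - done,
                            config$thresholds$t1, config$thresholds$t2)
      mesh$pos <- out$pos
      mesh$clock <- mesh$clock + out$steps * dt
      done <- done + out$steps
      if (out$status == 0L) break
      if (out$status == 3L)
        stop("numerical instability (non-finite positions) at t = ",
             round(mesh$clock, 3), " h")
      if (out$status == 1L) {
        e <- c(fl$ev1[out$info] + 1L, fl$ev2[out$info] + 1L)
        nv0 <- n_vertices(mesh)
        m2 <- apply_t1(mesh, e, config$thresholds)
        if (isTRUE(attr(m2, "t1_failed"))) {
          skip_t1 <- c(skip_t1, edge_key(e[1], e[2]))
          mesh$split_cooldown <- m2$split_cooldown
        } else {
          attr(m2, "t1_failed") <- NULL
          mesh <- m2
          topo_changed <- TRUE
          ed <- NULL
          if (n_vertices(mesh) != nv0) {
            needs_sweep <- TRUE        # boundary collapse remapped ids
            skip_t1 <- numeric(0)
          }
          if (validate) check_state(mesh, "apply_t1")
        }
      } else if (out$status == 2L) {
        m2 <- tryCatch({
          if (length(mesh$cells[[out$info]]) == 3)
            apply_t2(mesh, out$info, config$thresholds$t2)
          else
            remove_cell_to_point(mesh, out$info)
        }, error = function(e) NULL)
        if (is.null(m2) || isTRUE(attr(m2, "t2_failed")) ||
            identical(m2$cells, mesh$cells)) {
          mesh <- thyromorph_cool_cell(mesh, out$info)
          break
        }
        mesh <- m2
        skip_t1 <- numeric(0)
        topo_changed <- TRUE
        needs_sweep <- TRUE   # extrusion can leave a high-degree vertex
        ed <- NULL
        if (validate) check_state(mesh, "apply_t2")
      }
      # vertex ids may have been remapped; rebuild the motile force field
      if (topo_changed) {
        if (is.null(ed)) ed <- edge_struct(mesh)
        addF <- if (config$chemotaxis) chemo_forces(mesh, config, ed) else
          matrix(0, n_vertices(mesh), 2)
      }
    }
    step_i <- step_i + done
    dte <- done * dt

    # shared geometry for this chunk's biology
    if (is.null(ed)) ed <- edge_struct(mesh)
    cp <- c(0L, cumsum(lengths(mesh$cells)))
    g <- cell_geom_cpp(mesh$pos, cp, unlist(mesh$cells, use.names = FALSE) - 1L)
    geom <- list(ed = ed, adj = adj_struct(mesh, ed),
                 cen = cbind(g$cx, g$cy), areas = g$area)

    excl <- integer(0)
    if (config$polarity) {
      mesh <- update_polarity(mesh, config$pol, dte, config$lumen, geom = geom)
      mesh <- grow_lumina(mesh, config$lumen, dte, adj = geom$adj)
      for (cell in check_polarised_division(mesh, config$pol, adj = geom$adj)) {
        res <- create_lumen(mesh, cell, config$lumen)
        if (is.null(res)) next
        mesh <- res$mesh
        topo_changed <- TRUE
        if (validate) check_state(mesh, "create_lumen")
        excl <- c(excl, res$lumen_id, res$epithelial_id)
        push_event(tibble::tibble(time = mesh$clock, event = "lumen_created",
                                  cell_type = "lumen",
                                  generation = NA_integer_,
                                  cell = cell, daughter = res$lumen_id))
      }
    }
    if (config$proliferation) {
      res <- advance_cycles_and_divide(mesh, config$prolif, dte, exclude = excl)
      mesh <- res$mesh
      if (!is.null(res$events)) {
        push_event(res$events); topo_changed <- TRUE
        if (validate) check_state(mesh, "advance_cycles_and_divide")
      }
    } else {
      mesh$age <- mesh$age + dte
    }
    if (config$stalk_division) {
      res <- stalk_divide_if_elongated(mesh, config$endo)
      mesh <- res$mesh
      if (!is.null(res$events)) {
        push_event(res$events); topo_changed <- TRUE
        if (validate) check_state(mesh, "stalk_divide_if_elongated")
      }
    }
    if (mesh$clock >= next_branch) {
      if (mesh$clock < config$endo$branch_addition_cutoff) {
        res <- suppressWarnings(add_endothelial_branch(mesh, config$endo,
                                                       endo_A0 = config$endo_A0))
        mesh <- res$mesh
        if (res$added) {
          topo_changed <- TRUE
          needs_sweep <- TRUE
          if (validate) check_state(mesh, "add_endothelial_branch")
          push_event(tibble::tibble(time = mesh$clock, event = "branch_added",
                                    cell_type = "endothelial_tip",
                                    generation = NA_integer_,
                                    cell = res$tip, daughter = res$stalk))
        }
      }
      next_branch <- mesh$clock + stats::rexp(1, config$endo$branch_addition_rate)
    }
    if (length(mesh$rosettes)) needs_sweep <- TRUE
    if (needs_sweep) {
      mesh <- rearrangement_sweep(mesh, config$thresholds, on_cap = "warn")
      skip_t1 <- numeric(0)
      topo_changed <- TRUE
      if (validate) check_state(mesh, "rearrangement_sweep")
    } else {
      hit <- find_t3_candidate(mesh, config$thresholds$t3_tol)
      if (!is.null(hit)) {
        mesh <- apply_t3(mesh, hit$vertex, hit$edge, config$thresholds$t3_tol)
        if (validate) check_state(mesh, "apply_t3")
        mesh <- rearrangement_sweep(mesh, config$thresholds, on_cap = "warn")
        skip_t1 <- numeric(0)
        topo_changed <- TRUE
        if (validate) check_state(mesh, "t3_sweep")
      }
    }
    if (topo_changed) {
      mesh <- classify_peripherality(mesh)
      ed <- NULL
      addF <- NULL
    }
    if (mesh$clock >= next_stats - 1e-9) {
      stats_rows[[length(stats_rows) + 1L]] <-
        compute_summary_stats(mesh, config$prolif)
      next_stats <- next_stats + config$stats_every
      if (isTRUE(getOption("thyromorph.progress")))
        message(sprintf("t = %.1f h | %d cells", mesh$clock, n_cells(mesh)))
      cp <- getOption("thyromorph.checkpoint")
      if (!is.null(cp)) saveRDS(mesh, cp)
    }
  }
  structure(list(mesh = mesh,
                 stats = do.call(rbind, stats_rows),
                 events = if (length(events)) do.call(rbind, events) else
                   tibble::tibble(time = numeric(0), event = character(0),
                                  cell_type = character(0),
                                  generation = integer(0),
                                  cell = integer(0), daughter = integer(0)),
                 config = config),
            class = "tissue_run")
}

check_state <- function(mesh, where) {
  ok <- tryCatch({ mesh_check(mesh, check_simple = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stop("invariant violation after ", where, " at t = ", mesh$clock,
         ": ", conditionMessage(ok))
  invisible(TRUE)
}

#' @export
print.tissue_run <- function(x, ...) {
  last <- x$stats[nrow(x$stats), ]
  cat("<tissue_run> ", nrow(x$stats), " samples to t = ",
      format(last$time, digits = 4), " h\n", sep = "")
  cat(sprintf("  cells: %d | endothelial fraction: %.3f | lumina: %d | islets: %d\n",
              last$n_cells, last$endothelial_fraction, last$lumen_count,
              last$islet_count))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the statistics trajectory of a run
#'
#' @param x a `tissue_run`.
#' @param ... unused.
#' @return The per-sample-time statistics tibble.
#' @export
tidy.tissue_run <- function(x, ...) x$stats

#' One-row summary of a run
#'
#' @param x a `tissue_run`.
#' @param ... unused.
#' @return Final-state summary tibble (one row).
#' @export
glance.tissue_run <- function(x, ...) {
  last <- x$stats[nrow(x$stats), , drop = FALSE]
  first_lumen <- if (any(x$events$event == "lumen_created"))
    min(x$events$time[x$events$event == "lumen_created"]) else NA_real_
  tibble::tibble(duration = last$time, n_cells = last$n_cells,
                 endothelial_fraction = last$endothelial_fraction,
                 lumen_count = last$lumen_count,
                 islet_count = last$islet_count,
                 first_lumen_time = first_lumen,
                 n_divisions = sum(x$events$event == "division"))
}
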