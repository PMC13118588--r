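#' Autosampler fluid network
#'
#' Port-level model of the two-valve autosampling flow path: an
#' eight-position selector valve whose center port serves the syringe
#' buffer line, and a six-port two-position valve carrying the sample
#' loop, sampling needle, pump and column. The default wiring mirrors the
#' reference build:
#'
#' * syringe -> selector center via a 50 cm x 200 um transfer line
#' * selector port 1 -> waste; port 3 -> solvent A reservoir;
#'   port 6 -> two-position valve port 1 via a 15 cm x 200 um line
#'   (selector ports 2, 4, 5, 7 and 8 exist but are unused)
#' * sample loop (13 cm x 100 um, nominally 1 uL) across two-position
#'   ports 2 and 5; sampling needle on port 6; pump on port 3 and column
#'   on port 4, each via 75 cm x 20 um lines
#'
#' The six-port pairing convention is: position A (LOAD) connects
#' (1-2)(3-4)(5-6) — needle, loop and syringe in series while the pump
#' flows straight to the column — and position B (INJECT) connects
#' (2-3)(4-5)(6-1), placing the loop online between pump and column.
#'
#' @param loop a [capillary_spec()] for the sample loop.
#' @param loop_volume_ul optional override of the loop volume in uL (e.g.
#'   the nominal 1 uL instead of the 1.021 uL geometric volume).
#' @param needle_dead_volume_ul fluid-path volume between the needle tip
#'   and the loop entrance, uL. The needle's true dimensions are not part
#'   of the autosampler description, so this is explicit configuration;
#'   the default 3.2 uL makes the reference underfill/overfill recipes
#'   (500 nL + 3500 nL, 1700 nL + 3000 nL) geometrically valid.
#' @return a `fluid_network` object.
#' @export
fluid_network <- function(loop = capillary_spec(13, 100, "sample loop"),
                          loop_volume_ul = NULL,
                          needle_dead_volume_ul = 3.2) {
  if (needle_dead_volume_ul <= 0) {
    stop_nanosampler("needle dead volume must be positive", "network_error")
  }
  loop_vol <- loop_volume_ul %||% capillary_volume(loop)
  seg <- function(from, to, label, length_cm = NA, id_um = NA, volume_ul = NULL) {
    vol <- volume_ul %||% capillary_volume(capillary_spec(length_cm, id_um))
    tibble::tibble(from = from, to = to, label = label,
                   length_cm = length_cm, id_um = id_um, volume_ul = vol)
  }
  segments <- dplyr::bind_rows(
    seg("syringe", "sel_center", "syringe line", 50, 200),
    seg("sel_1", "waste", "waste line", 30, 200),
    seg("sel_3", "solventA", "solvent A line", 10, 200),
    seg("sel_6", "tp_1", "transfer line", 15, 200),
    seg("tp_2", "tp_5", "loop", loop$length_cm, loop$id_um, volume_ul = loop_vol),
    seg("tp_6", "needle", "needle", volume_ul = needle_dead_volume_ul),
    seg("tp_3", "pump", "pump line", 75, 20),
    seg("tp_4", "column", "column line", 75, 20)
  )
  nodes <- unique(c(segments$from, segments$to,
                    paste0("sel_", 1:8), paste0("tp_", 1:6), "sel_center"))
  structure(
    list(
      segments = segments,
      nodes = nodes,
      loop_volume_ul = loop_vol,
      needle_dead_volume_ul = needle_dead_volume_ul,
      selector_ports = 8L,
      two_position_pairs = list(
        A = list(c(1, 2), c(3, 4), c(5, 6)),
        B = list(c(2, 3), c(4, 5), c(6, 1))
      )
    ),
    class = "fluid_network"
  )
}

#' @export
print.fluid_network <- function(x, ...) {
  cat(sprintf("<fluid_network> %d segments, loop %.4g uL, needle dead volume %.4g uL\n",
              nrow(x$segments), x$loop_volume_ul, x$needle_dead_volume_ul))
  invisible(x)
}

valve_edges <- function(network, selector, two_position) {
  selector <- as.integer(selector)
  if (selector < 1 || selector > network$selector_ports) {
    stop_nanosampler("selector position out of range", "valve_error")
  }
  pairs <- network$two_position_pairs[[toupper(two_position)]]
  if (is.null(pairs)) {
    stop_nanosampler("two-position state must be A or B", "valve_error")
  }
  dplyr::bind_rows(
    tibble::tibble(from = "sel_center", to = paste0("sel_", selector),
                   label = sprintf("selector@%d", selector),
                   length_cm = NA_real_, id_um = NA_real_, volume_ul = 0),
    purrr::map_dfr(pairs, function(p) {
      tibble::tibble(from = paste0("tp_", p[1]), to = paste0("tp_", p[2]),
                     label = sprintf("valve %d-%d", p[1], p[2]),
                     length_cm = NA_real_, id_um = NA_real_, volume_ul = 0)
    })
  )
}

#' Active flow path between two endpoints
#'
#' Given the valve states, finds the unique open path between two
#' endpoints (by breadth-first search over segments plus the port pairs
#' each valve position connects) and returns the ordered traversed
#' segments with their volumes. In LOAD (`two_position = "A"`, selector
#' at 6) the path needle -> loop -> selector -> syringe exists while
#' pump -> column bypasses the loop; in INJECT (`"B"`) the path
#' pump -> loop -> column exists.
#'
#' @param network a [fluid_network()].
#' @param from,to endpoint node names, e.g. `"needle"`, `"syringe"`,
#'   `"pump"`, `"column"`, `"waste"`, `"solventA"`.
#' @param selector selector valve position (1..8).
#' @param two_position two-position valve state, `"A"` (LOAD) or `"B"`
#'   (INJECT).
#' @return a tibble of traversed segments in order from `from` to `to`
#'   (zero-volume valve links omitted), or `NULL` if the endpoints are not
#'   connected in this valve state.
#' @export
active_path <- function(network, from, to, selector = 6, two_position = "A") {
  if (!from %in% network$nodes || !to %in% network$nodes) {
    missing <- setdiff(c(from, to), network$nodes)
    stop_nanosampler(sprintf("unknown endpoint(s): %s", paste(missing, collapse = ", ")),
                     "network_error")
  }
  edges <- dplyr::bind_rows(network$segments,
                            valve_edges(network, selector, two_position))
  # undirected BFS
  adj <- split(
    c(seq_len(nrow(edges)), seq_len(nrow(edges))),
    c(edges$from, edges$to)
  )
  visited <- stats::setNames(rep(FALSE, length(network$nodes)), network$nodes)
  prev_edge <- stats::setNames(rep(NA_integer_, length(network$nodes)), network$nodes)
  prev_node <- stats::setNames(rep(NA_character_, length(network$nodes)), network$nodes)
  queue <- from
  visited[from] <- TRUE
  while (length(queue) > 0 && !visited[to]) {
    node <- queue[1]
    queue <- queue[-1]
    for (ei in adj[[node]] %||% integer(0)) {
      other <- if (edges$from[ei] == node) edges$to[ei] else edges$from[ei]
      if (!visited[other]) {
        visited[other] <- TRUE
        prev_edge[other] <- ei
        prev_node[other] <- node
        queue <- c(queue, other)
      }
    }
  }
  if (!visited[to]) {
    return(NULL)
  }
  path_edges <- integer(0)
  node <- to
  while (node != from) {
    path_edges <- c(prev_edge[[node]], path_edges)
    node <- prev_node[[node]]
  }
  out <- edges[path_edges, ]
  out$enters_at <- c(from, if (nrow(out) > 1) {
    vapply(seq_len(nrow(out) - 1), function(i) {
      # node shared between consecutive edges
      intersect(c(out$from[i], out$to[i]), c(out$from[i + 1], out$to[i + 1]))[1]
    }, character(1))
  })
  dplyr::filter(out, .data$volume_ul > 0)
}

#' One-dimensional sample-plug state
#'
#' Sample plugs are tracked as sharp, non-overlapping intervals of path
#' volume measured in uL from the needle tip toward the syringe
#' (`upstream` > `downstream`; the downstream boundary is nearer the
#' tip). Fluid is treated as incompressible with no dispersion, so plug
#' widths are invariant under advection — the model the volumetric
#' injection accounting assumes.
#'
#' @param plugs a tibble with columns `label`, `upstream`, `downstream`
#'   (uL from the tip); defaults to no plugs.
#' @return a `plug_state` object (a tibble subclass).
#' @export
plug_state <- function(plugs = NULL) {
  plugs <- plugs %||% tibble::tibble(label = character(),
                                     upstream = numeric(), downstream = numeric())
  plugs <- tibble::as_tibble(plugs)
  if (nrow(plugs) > 0) {
    if (any(plugs$downstream < 0) || any(plugs$upstream <= plugs$downstream)) {
      stop_nanosampler("plug boundaries must satisfy upstream > downstream >= 0",
                       "plug_error")
    }
    plugs <- dplyr::arrange(plugs, .data$downstream)
    if (nrow(plugs) > 1 &&
        any(plugs$downstream[-1] < plugs$upstream[-nrow(plugs)] - 1e-12)) {
      stop_nanosampler("plugs must not overlap", "plug_error")
    }
  }
  class(plugs) <- c("plug_state", class(tibble::tibble()))
  plugs
}

#' Advect plugs along the active path
#'
#' Shifts every plug boundary by `volume` uL toward the syringe
#' (aspiration at the tip) or toward the tip (dispense). Plug widths are
#' preserved; a plug pushed past the needle tip (dispense) or past the end
#' of the path (aspiration) is truncated or removed with a warning, and
#' the lost volume is recorded in the `lost_volume_ul` attribute.
#'
#' @param state a [plug_state()].
#' @param volume volume to advect, uL (>= 0); unit strings accepted.
#' @param direction `"aspirate"` (toward syringe) or `"dispense"`.
#' @param path_volume total open path volume from the tip, uL; boundaries
#'   beyond it are truncated on aspiration.
#' @return the new `plug_state`.
#' @export
advance_plugs <- function(state, volume, direction = c("aspirate", "dispense"),
                          path_volume = Inf) {
  direction <- match.arg(direction)
  volume <- as_microliters(volume)
  if (volume < 0) {
    stop_nanosampler("advection volume must be nonnegative", "plug_error")
  }
  shift <- if (direction == "aspirate") volume else -volume
  plugs <- tibble::as_tibble(state)
  lost <- 0
  if (nrow(plugs) > 0) {
    plugs$upstream <- plugs$upstream + shift
    plugs$downstream <- plugs$downstream + shift
    below <- pmax(0, -plugs$downstream)          # expelled from the tip
    above <- pmax(0, plugs$upstream - path_volume)  # past the path end
    lost <- sum(pmin(below, plugs$upstream - plugs$downstream)) +
      sum(pmin(above, plugs$upstream - plugs$downstream))
    plugs$downstream <- pmax(plugs$downstream, 0)
    plugs$upstream <- pmin(plugs$upstream, path_volume)
    gone <- plugs$upstream <= plugs$downstream
    if (lost > 1e-12) {
      warn_nanosampler(
        sprintf("%.4g uL of plug volume left the path (%d plug(s) removed)",
                lost, sum(gone)),
        "plug_truncated"
      )
    }
    plugs <- plugs[!gone, ]
  }
  out <- plug_state(plugs)
  attr(out, "lost_volume_ul") <- lost
  out
}

#' @rdname advance_plugs
#' @param label label of the newly aspirated plug.
#' @export
aspirate_plug <- function(state, volume, label = "sample", path_volume = Inf) {
  volume <- as_microliters(volume)
  state <- advance_plugs(state, volume, "aspirate", path_volume)
  plug_state(dplyr::bind_rows(
    tibble::tibble(label = label, upstream = volume, downstream = 0),
    tibble::as_tibble(state)
  ))
}

#' Plan a loop injection (underfill or overfill)
#'
#' Injection preparation aspirates `sample_volume` of sample at the needle
#' tip followed by `chase_volume` of solvent A, placing the sample plug on
#' the interval `[chase, chase + sample]` uL from the tip. The loop
#' occupies `[D, D + V_loop]` where `D` is the needle dead volume. An
#' *underfill* plan is valid when the plug lies entirely inside the loop
#' (injected volume = sample volume); an *overfill* plan is valid when the
#' plug covers the whole loop (injected volume = loop volume). Geometric
#' impossibilities yield an invalid plan with a diagnostic rather than an
#' error, mirroring how the instrument would report a method check.
#'
#' @param network a [fluid_network()].
#' @param mode `"underfill"` or `"overfill"`.
#' @param sample_volume_nl,chase_volume_nl sample and chase volumes in nL
#'   (unit strings like `"500 nL"` accepted).
#' @return an `injection_plan` object; see [tidy.injection_plan()].
#' @examples
#' net <- fluid_network()
#' plan_injection(net, "underfill", 500, 3500)
#' @export
plan_injection <- function(network, mode = c("underfill", "overfill"),
                           sample_volume_nl, chase_volume_nl) {
  mode <- match.arg(mode)
  sample_ul <- if (is.character(sample_volume_nl)) {
    as_microliters(sample_volume_nl)
  } else {
    as.numeric(sample_volume_nl) / 1000
  }
  chase_ul <- if (is.character(chase_volume_nl)) {
    as_microliters(chase_volume_nl)
  } else {
    as.numeric(chase_volume_nl) / 1000
  }
  if (sample_ul <= 0 || chase_ul <= 0) {
    stop_nanosampler("sample and chase volumes must be positive", "plan_error")
  }
  D <- network$needle_dead_volume_ul
  v_loop <- network$loop_volume_ul
  loop_interval <- c(start = D + v_loop, end = D)
  plug_interval <- c(start = sample_ul + chase_ul, end = chase_ul)
  overlap <- max(0, min(plug_interval["start"], loop_interval["start"]) -
                    max(plug_interval["end"], loop_interval["end"]))
  valid <- FALSE
  diagnostic <- ""
  injected_ul <- overlap
  if (mode == "underfill") {
    if (sample_ul > v_loop) {
      diagnostic <- sprintf("sample volume %.4g uL exceeds loop capacity %.4g uL",
                            sample_ul, v_loop)
    } else if (chase_ul < D) {
      diagnostic <- sprintf(
        "chase volume %.4g uL is smaller than the needle dead volume %.4g uL; the plug cannot reach the loop",
        chase_ul, D)
    } else if (sample_ul + chase_ul > D + v_loop) {
      diagnostic <- "chase pushes the front of the sample plug past the loop exit"
    } else {
      valid <- TRUE
      injected_ul <- sample_ul
    }
  } else {
    if (chase_ul > D) {
      diagnostic <- sprintf(
        "chase volume %.4g uL pushes the plug rear past the loop entrance (dead volume %.4g uL)",
        chase_ul, D)
    } else if (sample_ul + chase_ul < D + v_loop) {
      diagnostic <- "sample plus chase does not fill the loop to its exit"
    } else {
      valid <- TRUE
      injected_ul <- v_loop
    }
  }
  injected_ul <- min(injected_ul, v_loop)
  structure(
    list(
      mode = mode,
      sample_volume_nl = sample_ul * 1000,
      chase_volume_nl = chase_ul * 1000,
      loop_interval = loop_interval,
      plug_interval = plug_interval,
      injected_volume_nl = injected_ul * 1000,
      valid = valid,
      diagnostic = if (valid) "ok" else diagnostic
    ),
    class = "injection_plan"
  )
}

#' @export
print.injection_plan <- function(x, ...) {
  cat(sprintf("<injection_plan> %s: sample %g nL + chase %g nL\n",
              x$mode, x$sample_volume_nl, x$chase_volume_nl))
  cat(sprintf("  plug [%.4g, %.4g] uL vs loop [%.4g, %.4g] uL from tip\n",
              x$plug_interval["end"], x$plug_interval["start"],
              x$loop_interval["end"], x$loop_interval["start"]))
  cat(sprintf("  %s — injected %g nL (%s)\n",
              if (x$valid) "VALID" else "INVALID", x$injected_volume_nl, x$diagnostic))
  invisible(x)
}

#' @rdname plan_injection
#' @param x an `injection_plan`.
#' @param ... unused.
#' @export
tidy.injection_plan <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    sample_volume_nl = x$sample_volume_nl,
    chase_volume_nl = x$chase_volume_nl,
    injected_volume_nl = x$injected_volume_nl,
    valid = x$valid,
    diagnostic = x$diagnostic
  )
}

#' Mass loaded by an injection plan
#'
#' @param plan a valid [plan_injection()] result.
#' @param concentration_ng_ul sample concentration in ng/uL.
#' @return injected mass in ng.
#' @examples
#' net <- fluid_network()
#' plan <- plan_injection(net, "underfill", 500, 3500)
#' injected_mass(plan, 20)   # 10 ng
#' @export
injected_mass <- function(plan, concentration_ng_ul) {
  if (!inherits(plan, "injection_plan")) {
    stop_nanosampler("plan must be an injection_plan", "plan_error")
  }
  if (!plan$valid) {
    stop_nanosampler(sprintf("cannot compute injected mass of an invalid plan: %s",
                             plan$diagnostic), "plan_error")
  }
  if (concentration_ng_ul < 0) {
    stop_nanosampler("concentration must be nonnegative", "plan_error")
  }
  plan$injected_volume_nl / 1000 * concentration_ng_ul
}

#' Between-injection loop flush
#'
#' Builds the method that flushes the sample loop with solvent A between
#' injections: with the two-position valve in LOAD, the syringe draws
#' solvent from the selector's solvent A port and then dispenses it back
#' out through the selector, transfer line, loop and needle, so every
#' dispensed microliter passes the loop segment. Volumes larger than the
#' syringe run in multiple draw/dispense cycles. The reference protocol
#' flushes with 25 uL of solvent A.
#'
#' @param network a [fluid_network()].
#' @param volume_ul total flush volume, uL (default 25).
#' @param syringe_capacity_ul syringe capacity per cycle, uL.
#' @return a `method_program` (see [parse_method()]) whose execution
#'   routes `volume_ul` of solvent through the loop; carries a
#'   `flush_volume_ul` attribute.
#' @export
flush_plan <- function(network, volume_ul = 25, syringe_capacity_ul = 25) {
  volume_ul <- as_microliters(volume_ul)
  if (volume_ul == 0) {
    warn_nanosampler("flush volume 0: no-op flush", "incomplete_flush")
    prog <- method_program("flush", list())
    attr(prog, "flush_volume_ul") <- 0
    return(prog)
  }
  if (volume_ul < network$loop_volume_ul) {
    warn_nanosampler(
      sprintf("flush volume %.4g uL is below the loop volume %.4g uL: incomplete flush",
              volume_ul, network$loop_volume_ul),
      "incomplete_flush"
    )
  }
  n_full <- floor(volume_ul / syringe_capacity_ul)
  residual <- volume_ul - n_full * syringe_capacity_ul
  cycles <- c(rep(syringe_capacity_ul, n_full), if (residual > 1e-12) residual)
  steps <- list(list(step = "valve_two_position", position = "A"))
  for (v in cycles) {
    steps <- c(steps, list(
      list(step = "valve_selector", port = 3),
      list(step = "aspirate", volume = v),
      list(step = "valve_selector", port = 6),
      list(step = "dispense", volume = v)
    ))
  }
  prog <- method_program("flush", steps)
  attr(prog, "flush_volume_ul") <- volume_ul
  prog
}
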