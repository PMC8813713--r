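#' Configuration of the two-layer cortical column
#'
#' Assembles and validates the configuration from which [buildNetwork()]
#' constructs a concrete network: population sizes, grid geometry, the local
#' connectivity table, channel densities and multiplier overrides.
#'
#' @param n_pyr_per_layer Number of pyramidal neurons per layer (default 100).
#' @param n_basket_per_layer Number of basket cells per layer (default 35).
#' @param grid_spacing Spacing of the cell grid, arbitrary units; distances
#'   enter the Gaussian connectivity kernel.
#' @param kernel If `TRUE` (default) synaptic weights fall off with distance
#'   as `exp(-d^2 / lamtha^2)` and delays grow as the inverse, per connection
#'   type; if `FALSE` connectivity is uniform all-to-all at the nominal weight.
#' @param params Fixed-parameter registry, see [defaultNetworkParams()].
#' @param local_connectivity Optional replacement connectivity table
#'   (data.frame with columns pre, post, receptor, weight, loc, lamtha, delay).
#' @param overrides Named numeric vector of multiplier overrides applied via
#'   [applyOverrides()] at build time; names must be in [overrideRegistry()].
#' @return An object of class `NetworkConfig`.
#' @export
networkConfig <- function(n_pyr_per_layer = 100, n_basket_per_layer = 35,
                          grid_spacing = 1, kernel = TRUE,
                          params = defaultNetworkParams(),
                          local_connectivity = NULL, overrides = numeric(0)) {
  if (!is.null(local_connectivity)) params$connectivity <- local_connectivity
  cfg <- structure(list(
    n_pyr_per_layer = n_pyr_per_layer,
    n_basket_per_layer = n_basket_per_layer,
    grid_spacing = grid_spacing,
    kernel = isTRUE(kernel),
    params = params,
    overrides = overrides
  ), class = "NetworkConfig")
  if (length(overrides)) cfg <- applyOverrides(cfg, overrides)
  validateNetworkConfig(cfg)
  cfg
}

validateNetworkConfig <- function(cfg) {
  chkCount <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0 || x != round(x))
      stop(sprintf("'%s' must be a single non-negative integer", nm),
           call. = FALSE)
  }
  chkCount(cfg$n_pyr_per_layer, "n_pyr_per_layer")
  chkCount(cfg$n_basket_per_layer, "n_basket_per_layer")
  if (cfg$grid_spacing <= 0) stop("'grid_spacing' must be positive", call. = FALSE)
  con <- cfg$params$connectivity
  need <- c("pre", "post", "receptor", "weight", "loc", "lamtha", "delay")
  if (!all(need %in% names(con)))
    stop("'local_connectivity' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(c(con$pre, con$post)), POPULATIONS)
  if (length(bad))
    stop("'local_connectivity' names unknown populations: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(con$weight < 0)) stop("'local_connectivity$weight' must be >= 0", call. = FALSE)
  if (any(con$delay < 0)) stop("'local_connectivity$delay' must be >= 0", call. = FALSE)
  for (ct in names(cfg$params$cells)) {
    ch <- cfg$params$cells[[ct]]$channels
    for (cls in names(ch))
      if (any(ch[[cls]] < 0))
        stop(sprintf("channel density for %s/%s must be >= 0", ct, cls),
             call. = FALSE)
  }
  invisible(cfg)
}

#' Registry of named parameter-class overrides
#'
#' Each entry names a class of fixed parameters that can be scaled by a single
#' multiplier through [applyOverrides()], mirroring the targeted network
#' manipulations used to probe alternative mechanisms for the left-hemisphere
#' N100m reduction: dividing all synaptic weights onto inhibitory cells by 10,
#' or cutting the layer-V pyramidal calcium density.
#'
#' @return Named character vector: registry names with a short description.
#' @export
overrideRegistry <- function() {
  c(inhibitory_targeting_weights =
      "synaptic conductances of all local connections onto basket cells",
    L5_pyr_calcium_density =
      "high-voltage-activated calcium channel density in soma and dendrites of layer V pyramidal cells")
}

#' Scale a named class of fixed parameters
#'
#' Returns a new configuration in which every parameter in `class` is
#' multiplied by the given factor; all other parameters are untouched.
#'
#' @param config A `NetworkConfig`.
#' @param overrides Named numeric vector, names from [overrideRegistry()],
#'   values >= 0.
#' @return A new `NetworkConfig`.
#' @export
applyOverrides <- function(config, overrides) {
  stopifnot(inherits(config, "NetworkConfig"))
  if (!length(overrides)) return(config)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
    stop("'overrides' must be a named numeric vector", call. = FALSE)
  unknown <- setdiff(names(overrides), names(overrideRegistry()))
  if (length(unknown))
    stop("unknown override class(es): ", paste(unknown, collapse = ", "),
         "; registry: ", paste(names(overrideRegistry()), collapse = ", "),
         call. = FALSE)
  if (any(overrides < 0)) stop("override multipliers must be >= 0", call. = FALSE)
  for (nm in names(overrides)) {
    m <- overrides[[nm]]
    if (nm == "inhibitory_targeting_weights") {
      sel <- config$params$connectivity$post %in% BASKET_POPS
      config$params$connectivity$weight[sel] <-
        config$params$connectivity$weight[sel] * m
    } else if (nm == "L5_pyr_calcium_density") {
      for (cls in names(config$params$cells$L5Pyr$channels)) {
        ch <- config$params$cells$L5Pyr$channels[[cls]]
        if ("ca" %in% names(ch))
          config$params$cells$L5Pyr$channels[[cls]]["ca"] <- ch[["ca"]] * m
      }
    }
  }
  config
}

# grid positions; pyramidal cells on a square grid, baskets spread evenly
# over the same extent
popPositions <- function(n, extent, spacing) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  side <- ceiling(sqrt(n))
  if (side < 2) return(matrix(c(extent / 2, extent / 2), ncol = 2))
  g <- seq(0, extent, length.out = side)
  xy <- as.matrix(expand.grid(x = g, y = g))[seq_len(n), , drop = FALSE]
  xy * 1
}

#' Build the cortical-column network
#'
#' Instantiates the four populations (layer II/III and layer V pyramidal and
#' basket cells), their compartments and channels, and the local synaptic
#' connectivity, in a form ready for the compiled integrator.  Deterministic
#' given the configuration.
#'
#' @param config A `NetworkConfig` from [networkConfig()].
#' @return An object of class `Network`.
#' @export
buildNetwork <- function(config = networkConfig()) {
  stopifnot(inherits(config, "NetworkConfig"))
  validateNetworkConfig(config)
  p <- config$params
  npyr <- config$n_pyr_per_layer
  nbask <- config$n_basket_per_layer
  counts <- c(L2Pyr = npyr, L2Basket = nbask, L5Pyr = npyr, L5Basket = nbask)

  # --- per-type compartment templates ----------------------------------
  templates <- lapply(names(p$cells), function(ct) {
    cell <- p$cells[[ct]]
    sec <- cell$sections
    ns <- nrow(sec)
    idx <- stats::setNames(seq_len(ns), sec$name)
    parent <- ifelse(is.na(sec$parent), -1L, idx[sec$parent] - 1L)
    area <- pi * sec$diam * sec$L
    # z-coordinates of section start/centre, stacking along the apical axis
    zstart <- numeric(ns); zcenter <- numeric(ns)
    for (i in seq_len(ns)) {
      if (is.na(sec$parent[i])) {
        zstart[i] <- 0
      } else {
        pi_ <- idx[[sec$parent[i]]]
        zstart[i] <- if (identical(sec$attach[i], "start")) zstart[pi_]
                     else zstart[pi_] + sec$orient[pi_] * sec$L[pi_]
      }
      zcenter[i] <- zstart[i] + sec$orient[i] * sec$L[i] / 2
    }
    dz <- numeric(ns)
    for (i in seq_len(ns)) if (parent[i] >= 0)
      dz[i] <- zcenter[i] - zcenter[parent[i] + 1L]
    # axial conductance to parent (uS); R_MOhm = Ra * L' / (100 * A_cross)
    rhalf <- cell$Ra * (sec$L / 2) / (100 * pi * (sec$diam / 2)^2)
    ga <- numeric(ns)
    for (i in seq_len(ns)) if (parent[i] >= 0)
      ga[i] <- 1 / (rhalf[i] + rhalf[parent[i] + 1L])
    # channel conductances in uS (density S/cm2 * area um2 * 1e-2);
    # temperature factors of the Mainen-style channels are folded in here
    tadj_m <- 2.3^((p$constants$celsius - 23) / 10)
    dens <- function(i, chan) {
      cls <- if (sec$name[i] == "soma") "soma" else "dend"
      d <- cell$channels[[cls]]
      v <- if (chan %in% names(d)) d[[chan]] else 0
      if (chan == "ar" && !is.null(cell$ar_gradient))
        v <- v * exp(cell$ar_gradient * max(zcenter[i], 0))
      v
    }
    gc <- function(chan, tadj = 1)
      vapply(seq_len(ns), function(i) dens(i, chan) * area[i] * 1e-2 * tadj,
             numeric(1))
    list(
      type = ct, n_comp = ns, names = sec$name, parent = parent,
      area = area, dz = dz, ga = ga,
      cap = cell$cm * area * 1e-5,
      gleak = gc("leak"), eleak = rep(cell$el, ns),
      gna = gc("na"), gk = gc("kdr"), gkm = gc("km", tadj_m),
      gca = gc("ca", tadj_m), gkca = gc("kca", tadj_m),
      gcat = gc("cat"), gar = gc("ar"),
      sec_index = idx
    )
  })
  names(templates) <- names(p$cells)

  # --- instantiate cells ------------------------------------------------
  pops <- POPULATIONS[counts[POPULATIONS] > 0]
  cell_pop <- rep(pops, counts[pops])
  ncell <- length(cell_pop)
  pop_first <- cumsum(c(0, counts[pops]))[seq_along(pops)]
  names(pop_first) <- pops

  extent <- (ceiling(sqrt(max(npyr, 1))) - 1) * config$grid_spacing
  pos <- matrix(0, ncell, 2)
  for (pp in pops) {
    sel <- which(cell_pop == pp)
    pos[sel, ] <- popPositions(length(sel), max(extent, 1e-9), config$grid_spacing)
  }

  comp_counts <- vapply(cell_pop, function(pp) templates[[pp]]$n_comp, integer(1))
  cell_start <- cumsum(c(0L, comp_counts))[seq_len(ncell)]
  ncomp <- sum(comp_counts)

  take <- function(field) unlist(lapply(cell_pop, function(pp) templates[[pp]][[field]]),
                                 use.names = FALSE)
  parent <- unlist(lapply(seq_len(ncell), function(ci) {
    tp <- templates[[cell_pop[ci]]]
    ifelse(tp$parent < 0, -1L, tp$parent + cell_start[ci])
  }), use.names = FALSE)
  cellof <- rep(seq_len(ncell) - 1L, comp_counts)

  celltype_id <- stats::setNames(seq_along(POPULATIONS) - 1L, POPULATIONS)
  layer_of <- c(L2Pyr = 0L, L2Basket = 0L, L5Pyr = 1L, L5Basket = 1L)

  syn_tau1 <- syn_tau2 <- syn_e <- matrix(0, 4, 4)
  for (r in seq_along(RECEPTORS)) {
    syn_tau1[, r] <- p$synapses$tau1[[RECEPTORS[r]]]
    syn_tau2[, r] <- p$synapses$tau2[[RECEPTORS[r]]]
    syn_e[, r] <- p$synapses$e[[RECEPTORS[r]]]
  }
  for (ct in names(p$synapses$tau2_overrides %||% list())) {
    ov <- p$synapses$tau2_overrides[[ct]]
    syn_tau2[celltype_id[[ct]] + 1L, match(names(ov), RECEPTORS)] <- ov
  }

  net <- list(
    parent = as.integer(parent),
    cell = as.integer(cellof),
    celltype = as.integer(celltype_id[cell_pop]),
    layer = layer_of[cell_pop],
    is_pyr = as.integer(cell_pop %in% PYR_POPS),
    soma = as.integer(cell_start),             # soma is first compartment
    cell_start = as.integer(cell_start),
    cell_end = as.integer(cell_start + comp_counts - 1L),
    cap = take("cap"), ga = take("ga"), dz = take("dz"), area = take("area"),
    gleak = take("gleak"), eleak = take("eleak"),
    gna = take("gna"), gk = take("gk"), gkm = take("gkm"), gca = take("gca"),
    gkca = take("gkca"), gcat = take("gcat"), gar = take("gar"),
    syn_tau1 = syn_tau1, syn_tau2 = syn_tau2, syn_e = syn_e,
    params = p$constants
  )

  # --- local connectivity (CSR by presynaptic cell) ---------------------
  rec_id <- stats::setNames(seq_along(RECEPTORS) - 1L, RECEPTORS)
  con <- p$connectivity
  con <- con[con$pre %in% pops & con$post %in% pops & con$weight > 0, ,
             drop = FALSE]
  pieces <- vector("list", nrow(con))
  for (k in seq_len(nrow(con))) {
    pre_cells <- which(cell_pop == con$pre[k])
    post_cells <- which(cell_pop == con$post[k])
    if (!length(pre_cells) || !length(post_cells)) next
    secs <- targetSections(con$loc[k], con$post[k], p)
    comp_off <- templates[[con$post[k]]]$sec_index[secs] - 1L
    pr <- expand.grid(a = pre_cells, b = post_cells)
    pr <- pr[pr$a != pr$b, , drop = FALSE]  # no autapses
    d2 <- (pos[pr$a, 1] - pos[pr$b, 1])^2 + (pos[pr$a, 2] - pos[pr$b, 2])^2
    kern <- if (config$kernel && is.finite(con$lamtha[k]))
      exp(-d2 / con$lamtha[k]^2) else rep(1, nrow(pr))
    ww <- con$weight[k] * kern
    keep <- ww >= 1e-8
    if (!any(keep)) next
    pr <- pr[keep, , drop = FALSE]; ww <- ww[keep]; kern <- kern[keep]
    m <- length(comp_off); np <- nrow(pr)
    pieces[[k]] <- data.frame(
      src = rep(pr$a - 1L, each = m),
      comp = rep(cell_start[pr$b], each = m) + rep.int(comp_off, np),
      slot = rec_id[[con$receptor[k]]],
      w = rep(ww, each = m),
      delay = rep(con$delay[k] / pmax(kern, 1e-12), each = m)
    )
  }
  allc <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(allc))
    allc <- data.frame(src = integer(0), comp = integer(0), slot = integer(0),
                       w = numeric(0), delay = numeric(0))
  ord <- order(allc$src)
  src <- allc$src[ord]
  tgt_comp <- allc$comp; tgt_slot <- allc$slot; w <- allc$w; dl <- allc$delay
  conn_ptr <- c(0L, cumsum(tabulate(src + 1L, nbins = ncell)))
  net$conn_ptr <- as.integer(conn_ptr)
  net$conn_comp <- as.integer(tgt_comp[ord])
  net$conn_slot <- as.integer(tgt_slot[ord])
  net$conn_w <- w[ord]
  net$conn_delay <- dl[ord]

  structure(list(
    config = config, engine = net, templates = templates,
    populations = cell_pop, positions = pos,
    pop_sizes = counts[pops], pop_first = pop_first,
    n_cells = ncell, n_comp = ncomp,
    cache = new.env(parent = emptyenv())
  ), class = "Network")
}

# map a connection location label to target section names for a population
targetSections <- function(loc, post, params) {
  if (post %in% BASKET_POPS || loc == "soma") return("soma")
  if (loc == "proximal") return(c("basal_2", "basal_3", "apical_oblique"))
  if (loc == "distal") return("apical_tuft")
  stop("unknown location label: ", loc, call. = FALSE)
}

#' @export
print.Network <- function(x, ...) {
  cat("Cortical-column network\n")
  for (pp in names(x$pop_sizes))
    cat(sprintf("  %-9s %4d cells x %d compartments\n", pp, x$pop_sizes[[pp]],
                x$templates[[pp]]$n_comp))
  cat(sprintf("  %d compartments, %d local synapses, kernel %s\n",
              x$n_comp, length(x$engine$conn_w),
              if (x$config$kernel) "gaussian" else "uniform"))
  invisible(x)
}

#' @export
print.NetworkConfig <- function(x, ...) {
  cat(sprintf(
    "NetworkConfig: %d pyramidal + %d basket cells per layer, kernel %s\n",
    x$n_pyr_per_layer, x$n_basket_per_layer,
    if (x$kernel) "gaussian" else "uniform"))
  invisible(x)
}
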