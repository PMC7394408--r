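#' Pulse-shape gate for inclusion-bearing cells
#'
#' Cells carrying an inclusion concentrate fluorescence into a dense
#' particle, which narrows and heightens the fluorescence pulse at a given
#' pulse area. The gate is a supervised linear discriminant
#' ([MASS::lda()]) on the pulse-shape features `log(width)` and
#' `log(height) - log(area)` (pulse shape at fixed total signal — the
#' area normalization keeps expression level itself from driving the
#' gate), calibrated
#' on explicit negative-control (no inclusions) and positive-control
#' (inclusion-enriched) event sets. Given the calibration, flags are
#' deterministic.
#'
#' @param events event `data.frame` (schema of [simulate_population()]).
#' @param calibration list with elements `negative` and `positive`, each
#'   an event `data.frame` of at least 100 events. The positive set should
#'   be events known to carry inclusions, the negative set events known
#'   not to.
#' @return logical vector `has_inclusion`, one per event, with attributes
#'   `gate` (the fitted discriminant) and `separation` (Mahalanobis
#'   distance between calibration classes). Identical calibration
#'   populations raise an error; weakly separated ones
#'   (`separation < 1`) emit a separability warning (gate accuracy will
#'   be near chance).
#' @export
pulsa_gate <- function(events, calibration) {
  if (!all(c("negative", "positive") %in% names(calibration))) {
    stop("`calibration` must have `negative` and `positive` event sets")
  }
  neg <- calibration$negative; pos <- calibration$positive
  if (nrow(neg) < 100L || nrow(pos) < 100L) {
    stop("each calibration set needs at least 100 events")
  }
  feats <- function(ev) {
    ok <- ev$cerulean_area > 0 & ev$cerulean_width > 0 & ev$cerulean_height > 0
    if (!all(ok)) stop("pulse parameters must be positive for gating")
    cbind(w = log(ev$cerulean_width),
          h = log(ev$cerulean_height) - log(ev$cerulean_area))
  }
  xn <- feats(neg); xp <- feats(pos)
  train <- rbind(xn, xp)
  grp <- factor(rep(c("no_inclusion", "inclusion"), c(nrow(xn), nrow(xp))),
                levels = c("no_inclusion", "inclusion"))
  pooled <- ((nrow(xn) - 1L) * stats::cov(xn) + (nrow(xp) - 1L) * stats::cov(xp)) /
    (nrow(xn) + nrow(xp) - 2L)
  dmu <- colMeans(xp) - colMeans(xn)
  sep <- tryCatch(sqrt(drop(t(dmu) %*% solve(pooled, dmu))),
                  error = function(e) 0)
  if (!is.finite(sep) || sep < 1e-6) {
    stop("degenerate calibration: positive and negative populations are identical")
  }
  if (sep < 1) {
    warning(sprintf(
      "calibration populations barely separable (Mahalanobis distance %.2f); gate accuracy will be near chance", sep))
  }
  # equal priors: the gate is a boundary in shape space, not a prevalence
  # guess inherited from calibration set sizes
  gate <- MASS::lda(train, grouping = grp, prior = c(0.5, 0.5))
  flags <- stats::predict(gate, feats(events))$class == "inclusion"
  attr(flags, "gate") <- gate
  attr(flags, "separation") <- sep
  flags
}

#' Logarithmic expression bins
#'
#' Builds the binning scheme of the inclusion-fraction surface: cerulean
#' pulse area is assigned to `n_cerulean_bins` (default 20) log-uniform
#' bins spanning the range of positive recorded intensities; the modifier
#' (TMR) is assigned, independently per construct, to four ordered
#' categories — `none` below a detection floor, then `low` / `medium` /
#' `high` as log-uniform bins from the floor to that construct's maximum.
#' Bins are half-open `[lo, hi)` with the last bin closed, so a value on
#' an interior edge lands in the higher bin.
#'
#' @param events event `data.frame`.
#' @param n_cerulean_bins number of expression bins (default 20).
#' @param tmr_floor detection floor for the modifier; default is the 1st
#'   percentile of positive TMR values in `floor_reference` (a
#'   modifier-free calibration population) or, failing that, of `events`.
#' @param floor_reference optional event table used to set the floor.
#' @return object of class `bin_grid_spec`: `cerulean_edges` (length
#'   `n_cerulean_bins + 1`), `tmr` (per construct: `floor`, `edges`),
#'   `tmr_levels`.
#' @export
make_bins <- function(events, n_cerulean_bins = 20L, tmr_floor = NULL,
                      floor_reference = NULL) {
  cer <- events$cerulean_area[events$cerulean_area > 0]
  if (length(unique(cer)) < 2L) {
    stop("need at least 2 distinct positive cerulean intensities to bin")
  }
  cerulean_edges <- exp(seq(log(min(cer)), log(max(cer)),
                            length.out = n_cerulean_bins + 1L))
  if (is.null(tmr_floor)) {
    src <- if (!is.null(floor_reference)) floor_reference$tmr_area else events$tmr_area
    pos <- src[src > 0]
    tmr_floor <- if (length(pos)) unname(stats::quantile(pos, 0.01)) else Inf
  }
  constructs <- unique(events$construct)
  tmr <- lapply(constructs, function(cn) {
    v <- events$tmr_area[events$construct == cn]
    mx <- if (any(v >= tmr_floor)) max(v) else NA_real_
    edges <- if (is.na(mx) || mx <= tmr_floor) {
      NULL  # everything below floor: all events are "none"
    } else {
      exp(seq(log(tmr_floor), log(mx), length.out = 4L))
    }
    list(floor = tmr_floor, edges = edges)
  })
  names(tmr) <- constructs
  structure(list(cerulean_edges = cerulean_edges, tmr = tmr,
                 tmr_levels = c("none", "low", "medium", "high"),
                 n_cerulean_bins = as.integer(n_cerulean_bins)),
            class = "bin_grid_spec")
}

# half-open [lo, hi) bins, last bin closed; NA outside the edge range
.bin_assign <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[x < edges[1L] | x > edges[length(edges)]] <- NA_integer_
  i[i == length(edges)] <- length(edges) - 1L  # exact max
  i
}

#' Inclusion fraction per expression bin
#'
#' Assigns every event to a (cerulean bin, TMR category) cell and computes
#' the fraction of gated inclusion-positive events per cell — the
#' log-binned dose–response surface of aggregation. Events with
#' non-positive cerulean intensity cannot be log-binned; they are excluded
#' and counted in the QC attribute.
#'
#' @param events event `data.frame`.
#' @param flags logical `has_inclusion` vector aligned with `events`
#'   (e.g. from [pulsa_gate()], or the ground-truth column for scoring).
#' @param grid a `bin_grid_spec` from [make_bins()].
#' @return object of class `bin_grid`, a list per construct with `counts`,
#'   `n_inclusion` and `fraction` matrices (`n_cerulean_bins` rows, 4 TMR
#'   category columns; `fraction` is `NA` where `counts == 0`), plus
#'   attribute `qc` (excluded event counts). Use [as.data.frame()] for the
#'   tidy long form.
#' @export
inclusion_fraction <- function(events, flags, grid) {
  if (!inherits(grid, "bin_grid_spec")) stop("expected a `bin_grid_spec`")
  if (length(flags) != nrow(events)) stop("`flags` not aligned with `events`")
  usable <- events$cerulean_area > 0
  qc <- list(n_events = nrow(events), n_excluded_nonpositive = sum(!usable))
  ev <- events[usable, , drop = FALSE]
  fl <- flags[usable]
  cbin <- .bin_assign(ev$cerulean_area, grid$cerulean_edges)
  nb <- grid$n_cerulean_bins
  lv <- grid$tmr_levels
  per <- lapply(names(grid$tmr), function(cn) {
    sel <- ev$construct == cn & !is.na(cbin)
    tinfo <- grid$tmr[[cn]]
    tv <- ev$tmr_area[sel]
    tcat <- rep(1L, sum(sel))  # "none"
    if (!is.null(tinfo$edges)) {
      above <- tv >= tinfo$floor
      ti <- .bin_assign(tv[above], tinfo$edges)
      ti[is.na(ti)] <- 3L  # above recorded max (shouldn't happen): top bin
      tcat[above] <- 1L + ti
    }
    counts <- matrix(0L, nb, 4L, dimnames = list(NULL, lv))
    nincl <- matrix(0L, nb, 4L, dimnames = list(NULL, lv))
    tab <- table(factor(cbin[sel], levels = seq_len(nb)),
                 factor(tcat, levels = 1:4))
    tabi <- table(factor(cbin[sel][fl[sel]], levels = seq_len(nb)),
                  factor(tcat[fl[sel]], levels = 1:4))
    counts[] <- as.integer(tab)
    nincl[] <- as.integer(tabi)
    frac <- ifelse(counts > 0, nincl / counts, NA_real_)
    list(counts = counts, n_inclusion = nincl, fraction = frac)
  })
  names(per) <- names(grid$tmr)
  structure(per, class = "bin_grid", spec = grid, qc = qc)
}

#' @export
as.data.frame.bin_grid <- function(x, ...) {
  grid <- attr(x, "spec")
  edges <- grid$cerulean_edges
  lv <- grid$tmr_levels
  nb <- grid$n_cerulean_bins
  do.call(rbind, lapply(names(x), function(cn) {
    g <- x[[cn]]
    data.frame(
      construct = cn,
      cerulean_bin = rep(seq_len(nb), times = 4L),
      cerulean_bin_lo = rep(edges[seq_len(nb)], times = 4L),
      cerulean_bin_hi = rep(edges[-1L], times = 4L),
      tmr_category = rep(lv, each = nb),
      n = as.vector(g$counts),
      n_inclusion = as.vector(g$n_inclusion),
      fraction = as.vector(g$fraction),
      stringsAsFactors = FALSE
    )
  }))
}

#' Stall-reporter fluorescence ratios
#'
#' Per-event mCherry:GFP area ratios of the dual-fluorophore ribosome
#' stall reporter, summarized per construct by the median and
#' interquartile range. Ribosome stalling within the test sequence lowers
#' mCherry output relative to GFP, so the median ratio approximates
#' `1 - stall efficiency`. Events at or below the GFP expression floor are
#' excluded and counted.
#'
#' @param events event `data.frame` with positive `gfp_area` /
#'   `mcherry_area` for reporter-bearing events.
#' @param gfp_floor minimum GFP area for an event to be evaluable
#'   (default 0: any positive expression).
#' @return list of class `stall_summary`: `summary` (`data.frame` with
#'   `construct`, `n`, `n_excluded`, `median_ratio`, `iqr_lower`,
#'   `iqr_upper`) and `ratios` (per-event `data.frame`).
#' @export
stall_ratios <- function(events, gfp_floor = 0) {
  if (!all(c("gfp_area", "mcherry_area") %in% names(events))) {
    stop("event table lacks gfp_area / mcherry_area columns")
  }
  has <- is.finite(events$gfp_area) & is.finite(events$mcherry_area)
  ok <- has & events$gfp_area > gfp_floor
  if (!any(ok)) stop("no events above the GFP expression floor")
  ev <- events[ok, , drop = FALSE]
  ratio <- ev$mcherry_area / ev$gfp_area
  if (any(ratio < 0)) stop("negative fluorescence ratio encountered")
  per <- split(ratio, ev$construct)
  excl <- tapply(has & !ok, events$construct, sum)
  summ <- data.frame(
    construct = names(per),
    n = vapply(per, length, 0L),
    n_excluded = as.integer(excl[names(per)]),
    median_ratio = vapply(per, stats::median, 0),
    iqr_lower = vapply(per, function(r) unname(stats::quantile(r, 0.25)), 0),
    iqr_upper = vapply(per, function(r) unname(stats::quantile(r, 0.75)), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(summary = summ,
                 ratios = data.frame(event_id = ev$event_id,
                                     construct = ev$construct,
                                     ratio = ratio)),
            class = "stall_summary")
}

#' @export
print.stall_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
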