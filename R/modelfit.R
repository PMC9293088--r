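#' Signed perpendicular offsets from the 1:1 line
#'
#' For matched empirical/simulated value pairs, the perpendicular (Euclidean)
#' distance of the point `(emp, sim)` to the identity line `y = x`, signed
#' positive when the simulation overestimates:
#' `offset = (sim - emp) / sqrt(2)`.
#' @param emp,sim numeric vectors of equal length in matched node order.
#' @return numeric vector of signed offsets.
#' @export
perpendicular_offsets <- function(emp, sim) {
  if (length(emp) != length(sim))
    stop("empirical and simulated vectors differ in length (",
         length(emp), " vs ", length(sim), ")")
  (sim - emp) / sqrt(2)
}

#' Goodness-of-fit summaries of perpendicular offsets
#'
#' `spo` is the sum of absolute offsets (overall spread from the 1:1 line; a
#' larger value is a poorer fit), `mpo` the median absolute offset (robust to
#' outlier nodes), and `dmpo` the median of the signed offsets (direction of
#' the misfit: positive when the simulation typically overestimates).
#' @param offsets numeric vector of signed offsets from
#'   [perpendicular_offsets()].
#' @return scalar.
#' @export
spo <- function(offsets) {
  if (!length(offsets)) stop("no offsets supplied")
  sum(abs(offsets))
}

#' @rdname spo
#' @export
mpo <- function(offsets) {
  if (!length(offsets)) stop("no offsets supplied")
  stats::median(abs(offsets))
}

#' @rdname spo
#' @export
dmpo <- function(offsets) {
  if (!length(offsets)) stop("no offsets supplied")
  stats::median(offsets)
}

#' Fit summaries of simulated against empirical node statistics
#'
#' For every simulation scenario, response and species subset, computes SPO,
#' MPO and DMPO of the simulated node values against the empirical ones over
#' the empirical node set. Simulated values are first averaged over
#' replicates per node (when a `replicate` column is present).
#'
#' @param emp data frame of empirical per-node statistics with columns
#'   `node_id`, `species` and the response columns.
#' @param sims data frame of simulated per-node statistics with scenario
#'   columns (any of `d`, `W`, `k_mode`, `mut_model`), optionally
#'   `replicate`, plus `node_id` and the response columns.
#' @param responses response column names present in both tables.
#' @return data frame with one row per (scenario, response, species):
#'   scenario columns, `response`, `species`, `n_points`, `SPO`, `MPO`,
#'   `DMPO`.
#' @export
scenario_fit <- function(emp, sims, responses = c("AR", "Ho", "He")) {
  stopifnot(all(c("node_id", "species", responses) %in% names(emp)))
  scen_cols <- intersect(c("d", "W", "k_mode", "mut_model"), names(sims))
  stopifnot(length(scen_cols) > 0,
            all(c("node_id", responses) %in% names(sims)))
  # replicate mean per scenario x node
  agg <- stats::aggregate(
    sims[responses],
    by = sims[c(scen_cols, "node_id")], FUN = mean)
  scen_key <- do.call(paste, c(agg[scen_cols], sep = "\r"))
  out <- list()
  for (sk in unique(scen_key)) {
    sub <- agg[scen_key == sk, , drop = FALSE]
    lut <- stats::setNames(seq_len(nrow(sub)), sub$node_id)
    for (sp in unique(emp$species)) {
      e <- emp[emp$species == sp, , drop = FALSE]
      miss <- setdiff(e$node_id, sub$node_id)
      if (length(miss))
        stop("empirical node missing from simulation output: ",
             paste(miss, collapse = ", "))
      srows <- sub[lut[e$node_id], , drop = FALSE]
      for (resp in responses) {
        off <- perpendicular_offsets(e[[resp]], srows[[resp]])
        rec <- sub[1, scen_cols, drop = FALSE]
        rec$response <- resp
        rec$species <- sp
        rec$n_points <- length(off)
        rec$SPO <- spo(off); rec$MPO <- mpo(off); rec$DMPO <- dmpo(off)
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Win fraction of a focal parameter value across matched scenarios
#'
#' Compares every scenario carrying the focal value of one simulator
#' parameter against the scenarios differing only in that parameter. A
#' comparison context is a combination of the other scenario parameters,
#' response, species and goodness-of-fit measure (SPO and MPO by default);
#' within a context the focal value wins against an alternative when
#' `focal measure - alternative measure < 0` (strictly better fit). Exact
#' ties count as non-wins for both sides and are reported separately;
#' contexts with missing grid cells are skipped and counted.
#'
#' @param fits fit-summary table from [scenario_fit()] (scenario columns,
#'   `response`, `species`, measure columns).
#' @param parameter scenario column under test (e.g. `"d"`, `"W"`,
#'   `"k_mode"`).
#' @param focal_value the parameter value whose support is being assessed.
#' @param measures goodness-of-fit columns to include.
#' @return list with `parameter`, `focal_value`, `wins`, `ties`, `total`,
#'   `win_fraction` (= wins/total) and `skipped` contexts.
#' @export
parameter_win_fraction <- function(fits, parameter, focal_value,
                                   measures = c("SPO", "MPO")) {
  scen_cols <- intersect(c("d", "W", "k_mode", "mut_model"), names(fits))
  if (!parameter %in% scen_cols)
    stop("parameter must be one of: ", paste(scen_cols, collapse = ", "))
  other <- setdiff(scen_cols, parameter)
  ctx_cols <- c(other, "response", "species")
  ctx <- do.call(paste, c(fits[ctx_cols], sep = "\r"))
  vals <- unique(fits[[parameter]])
  alternatives <- setdiff(vals, focal_value)
  if (!focal_value %in% vals) stop("focal value absent from the fit table")
  wins <- ties <- total <- skipped <- 0L
  for (ck in unique(ctx)) {
    sub <- fits[ctx == ck, , drop = FALSE]
    foc <- sub[sub[[parameter]] == focal_value, , drop = FALSE]
    for (alt in alternatives) {
      al <- sub[sub[[parameter]] == alt, , drop = FALSE]
      for (ms in measures) {
        if (nrow(foc) != 1L || nrow(al) != 1L) { skipped <- skipped + 1L; next }
        dlt <- foc[[ms]] - al[[ms]]
        total <- total + 1L
        if (dlt < 0) wins <- wins + 1L
        else if (dlt == 0) ties <- ties + 1L
      }
    }
  }
  list(parameter = parameter, focal_value = focal_value, wins = wins,
       ties = ties, total = total,
       win_fraction = if (total > 0) wins / total else NA_real_,
       skipped = skipped)
}

#' Upper-triangle vector of a pairwise matrix over a node subset
#'
#' Helper for comparing pairwise differentiation matrices with
#' [perpendicular_offsets()]: extracts the upper triangle in a fixed node
#' order so empirical and simulated matrices vectorize identically.
#' @param m symmetric matrix with node ids as dimnames.
#' @param nodes node ids defining order and subset (default: matrix order).
#' @return numeric vector of the upper-triangle entries.
#' @export
upper_tri_vec <- function(m, nodes = NULL) {
  if (is.null(nodes)) nodes <- rownames(m)
  miss <- setdiff(nodes, rownames(m))
  if (length(miss)) stop("nodes absent from matrix: ",
                         paste(miss, collapse = ", "))
  mm <- m[nodes, nodes, drop = FALSE]
  mm[upper.tri(mm)]
}
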