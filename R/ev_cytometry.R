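# Small-particle flow-cytometry analysis of extracellular vesicles (EVs):
# FMO-derived gates, sequential gating, CEEV ratio and concentration, size
# binning, and replicate averaging.
#
# Event tables are plain data.frames with per-event fluorescence in three
# logical color channels — endo_ch (pooled CD31/CD144/CD105, AF488-like),
# lymph_platelet_ch (pooled CD3/CD41, Pacific-Blue-like), mal_ch (MAL,
# AF647-like) — plus diameter_nm, and acquisition metadata attached as the
# "acquisition" attribute (flowrate_ul_min, duration_s, dilution_factor).

.evChannels <- function() c("endo_ch", "lymph_platelet_ch", "mal_ch")

#' Acquisition metadata constructor
#'
#' @param flowrate_ul_min flow rate in uL/min (default 1.5).
#' @param duration_s acquisition time in seconds (default 120).
#' @param dilution_factor fold dilution of the plasma sample (>= 1).
#' @return named list; acquired volume (uL) = flowrate x duration.
#' @export
evAcquisition <- function(flowrate_ul_min = 1.5, duration_s = 120,
                          dilution_factor = 200) {
  stopifnot(flowrate_ul_min > 0, duration_s > 0, dilution_factor >= 1)
  list(flowrate_ul_min = flowrate_ul_min, duration_s = duration_s,
       dilution_factor = dilution_factor,
       volume_ul = flowrate_ul_min * duration_s / 60)
}

#' Derive positivity gates from FMO controls
#'
#' The positivity threshold of each color channel is a high percentile
#' (99.9 by default) of that channel's distribution in the
#' fluorescence-minus-one (FMO) control that omits the corresponding stain.
#' Gates are never derived from the stained sample itself.
#'
#' @param fmoTables named list of FMO event tables, one per channel in
#'   [.evChannels()] naming (e.g. `list(endo_ch = ..., ...)`).
#' @param percentile percentile of the FMO distribution (default 99.9).
#' @return list of class `GateSet`: per-channel `threshold`, plus
#'   `percentile` provenance.
#' @export
deriveGates <- function(fmoTables, percentile = 99.9) {
  stopifnot(percentile > 0, percentile < 100)
  chans <- .evChannels()
  missing <- setdiff(chans, names(fmoTables))
  if (length(missing))
    stop("missing FMO control(s) for channel(s): ", paste(missing, collapse = ", "))
  thr <- vapply(chans, function(ch) {
    v <- fmoTables[[ch]][[ch]]
    if (is.null(v)) stop("FMO table for ", ch, " lacks the column ", ch)
    as.numeric(quantile(v, percentile / 100))
  }, numeric(1))
  structure(list(threshold = thr, percentile = percentile),
            class = "GateSet")
}

#' Sequential gating of an EV event table
#'
#' Gating order mirrors the panel design: (1) events positive in the pooled
#' lymphocyte/platelet channel (CD3/CD41) are excluded; (2) remaining events
#' positive in the pooled endothelial channel are endothelial vesicles,
#' split by MAL positivity into CEEV (MAL+) and EEV-only (MAL-);
#' (3) MAL-positive non-endothelial events are labeled mal_other; everything
#' else is negative/debris. Labels partition the table.
#'
#' @param events event table with the three fluorescence columns.
#' @param gates a `GateSet` from [deriveGates()].
#' @return `events` with an added factor column `gate_label` in
#'   \{"platelet_lymphocyte", "ceev", "eev", "mal_other", "negative"\}.
#' @export
gateEvents <- function(events, gates) {
  thr <- gates$threshold
  stopifnot(all(.evChannels() %in% names(events)))
  pl <- events$lymph_platelet_ch > thr[["lymph_platelet_ch"]]
  endo <- events$endo_ch > thr[["endo_ch"]]
  mal <- events$mal_ch > thr[["mal_ch"]]
  lab <- rep("negative", nrow(events))
  lab[!pl & endo & mal] <- "ceev"
  lab[!pl & endo & !mal] <- "eev"
  lab[!pl & !endo & mal] <- "mal_other"
  lab[pl] <- "platelet_lymphocyte"
  events$gate_label <- factor(lab, levels = c("platelet_lymphocyte", "ceev",
                                              "eev", "mal_other", "negative"))
  events
}

#' CEEV ratio (percent)
#'
#' 100 x CEEV / (CEEV + EEV-only): the share of MAL-positive vesicles among
#' all vesicles of endothelial origin.
#'
#' @param ceev,eev counts of MAL-positive and MAL-negative endothelial
#'   events.
#' @return percent in [0, 100], or `NA` (attribute `flagged`) when no
#'   endothelial events exist.
#' @export
ceevRatio <- function(ceev, eev) {
  tot <- ceev + eev
  if (tot == 0) return(structure(NA_real_, flagged = TRUE))
  100 * ceev / tot
}

#' Event concentration in events/uL
#'
#' count / acquired volume x dilution factor, with the acquired volume
#' flowrate x duration (3 uL at the default 1.5 uL/min for 120 s).
#'
#' @param count event count.
#' @param acquisition metadata from [evAcquisition()].
#' @return events per uL of undiluted plasma.
#' @export
evConcentration <- function(count, acquisition) {
  if (acquisition$volume_ul <= 0) stop("acquired volume must be positive")
  count / acquisition$volume_ul * acquisition$dilution_factor
}

#' Size-distribution bin counts
#'
#' Half-open diameter bins [0,180), [180,600), [600,1000), [1000,Inf) nm by
#' default.
#'
#' @param diameters numeric vector of event diameters in nm.
#' @param breaks inner bin edges (default c(180, 600, 1000)).
#' @return named integer vector of bin counts (sums to the event count).
#' @export
sizeDistribution <- function(diameters, breaks = c(180, 600, 1000)) {
  edges <- c(0, breaks, Inf)
  cnt <- table(cut(diameters, edges, right = FALSE))
  setNames(as.integer(cnt),
           paste0("[", edges[-length(edges)], ",", edges[-1], ")"))
}

#' Summarize a gated EV sample
#'
#' Counts per gate, CEEV ratio, concentrations (events/uL, dilution
#' corrected) and the CEEV size distribution.
#'
#' @param gated gated event table from [gateEvents()].
#' @param acquisition metadata from [evAcquisition()] (taken from
#'   `attr(gated, "acquisition")` when omitted).
#' @return list (`EvSummary`): counts, ceev_ratio_pct, ceev_conc,
#'   eev_conc, mal_other_conc (events/uL), size_bins (CEEV population).
#' @export
summarizeEvSample <- function(gated, acquisition = attr(gated, "acquisition")) {
  if (is.null(acquisition)) stop("acquisition metadata required")
  n <- table(gated$gate_label)
  counts <- c(platelet_lymph_excluded = as.integer(n[["platelet_lymphocyte"]]),
              endo_mal_pos = as.integer(n[["ceev"]]),
              endo_mal_neg = as.integer(n[["eev"]]),
              mal_other = as.integer(n[["mal_other"]]),
              negative = as.integer(n[["negative"]]))
  list(counts = counts,
       ceev_ratio_pct = as.numeric(ceevRatio(counts[["endo_mal_pos"]],
                                             counts[["endo_mal_neg"]])),
       ceev_conc = evConcentration(counts[["endo_mal_pos"]], acquisition),
       eev_conc = evConcentration(counts[["endo_mal_pos"]] +
                                    counts[["endo_mal_neg"]], acquisition),
       mal_other_conc = evConcentration(counts[["mal_other"]], acquisition),
       size_bins = sizeDistribution(gated$diameter_nm[gated$gate_label == "ceev"]))
}

#' Average EV summaries across replicate aliquots
#'
#' Arithmetic mean of every numeric summary quantity across aliquots; a
#' single aliquot passes through with a warning.
#'
#' @param summaries list of [summarizeEvSample()] results (>= 1).
#' @return an averaged `EvSummary`-shaped list.
#' @export
averageReplicates <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  if (length(summaries) == 1) {
    warning("single aliquot: replicate averaging is a passthrough")
    return(summaries[[1]])
  }
  avg <- summaries[[1]]
  for (nm in names(avg)) {
    vals <- lapply(summaries, `[[`, nm)
    avg[[nm]] <- Reduce(`+`, vals) / length(vals)
  }
  avg
}
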