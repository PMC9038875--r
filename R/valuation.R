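#' Effective suitability of a parcel
#'
#' Collapses a parcel's suitability information to one scalar in [0, 1]. A
#' scalar parcel returns its suitability unchanged. A guild-resolved parcel
#' returns the convex combination of its nine (guild, stage) suitabilities
#' under the percent weights of its ecotype's column,
#' `S_eff = sum(w[g,s,e]/100 * S[g,s])`. Because the weights of a column sum
#' to 100, uniform mapped suitabilities collapse to themselves and the
#' result always stays in [0, 1].
#'
#' @param parcel A one-row [parcels()] tibble (or a list with the same
#'   fields).
#' @param weights A [guild_weight_table()]; required when the parcel carries
#'   a guild-resolved map.
#' @return Effective suitability, a scalar in [0, 1].
#' @export
effective_suitability <- function(parcel, weights = NULL) {
  m <- if (is.data.frame(parcel)) parcel$suit_map[[1]] else parcel$suit_map
  s <- if (is.data.frame(parcel)) parcel$suitability[1] else parcel$suitability
  eco <- if (is.data.frame(parcel)) parcel$ecotype[1] else parcel$ecotype
  if (is.null(m)) {
    if (is.na(s)) stop("parcel has neither scalar suitability nor a guild map")
    return(s)
  }
  if (is.null(weights)) {
    stop("guild-resolved parcel requires a guild weight table")
  }
  if (!(eco %in% colnames(weights))) {
    stop("no guild weight column for ecotype '", eco, "'")
  }
  keys <- guild_stage_keys()$keys
  if (!all(keys %in% names(m))) {
    stop("suitability map is missing keys: ",
         paste(setdiff(keys, names(m)), collapse = ", "))
  }
  sum(weights[keys, eco] / 100 * m[keys])
}

# vectorised over the rows of a parcel tibble
effective_suitabilities <- function(p, weights = NULL) {
  vapply(seq_len(nrow(p)), function(i)
    effective_suitability(p[i, , drop = FALSE], weights), numeric(1))
}

#' Weighted suitable area (WSA) per ecotype
#'
#' `WSA_e = sum over parcels of ecotype e of area * effective suitability`,
#' in suitability-weighted hectares. Retired parcels are excluded; the
#' result is additive over disjoint parcel sets.
#'
#' @param p A [parcels()] inventory.
#' @param weights Optional [guild_weight_table()] for guild-resolved parcels.
#' @return A tibble with columns `ecotype`, `area_ha`, `wsa`.
#' @export
compute_wsa <- function(p, weights = NULL) {
  p <- active_parcels(p)
  if (nrow(p) == 0) {
    return(tibble::tibble(ecotype = character(), area_ha = numeric(),
                          wsa = numeric()))
  }
  s <- effective_suitabilities(p, weights)
  tibble::tibble(ecotype = p$ecotype, area_ha = p$area_ha,
                 wsa = p$area_ha * s) |>
    dplyr::group_by(ecotype) |>
    dplyr::summarise(area_ha = sum(area_ha), wsa = sum(wsa), .groups = "drop")
}

#' Productivity-weighted suitable area (PWSA) per ecotype
#'
#' `PWSA_e = PPI_e * WSA_e`: the between-ecotype exchange into the common
#' trading currency (productivity-weighted hectares).
#'
#' @param wsa A tibble with columns `ecotype` and `wsa` (as returned by
#'   [compute_wsa()]).
#' @param ecotypes An ecotype/PPI table covering every ecotype in `wsa`.
#' @return The input with a `pwsa` column added; total PWSA as attribute
#'   `total_pwsa`.
#' @export
compute_pwsa <- function(wsa, ecotypes) {
  i <- match(wsa$ecotype, ecotypes$name)
  if (anyNA(i)) {
    stop("unknown ecotype key: ",
         paste(wsa$ecotype[is.na(i)], collapse = ", "))
  }
  wsa$pwsa <- ecotypes$ppi[i] * wsa$wsa
  attr(wsa, "total_pwsa") <- sum(wsa$pwsa)
  wsa
}

#' Full valuation of a ledger or inventory
#'
#' Rolls up area, WSA and PWSA per ecotype over all non-retired parcels.
#'
#' @param x A `service_area_ledger` or a [parcels()] inventory.
#' @param ecotypes,weights Used when `x` is a plain inventory.
#' @return A tibble of class `hb_valuation` with columns `ecotype`,
#'   `area_ha`, `wsa`, `pwsa` and attributes `total_area`, `total_wsa`,
#'   `total_pwsa`.
#' @export
valuation <- function(x, ecotypes = default_ecotypes(), weights = NULL) {
  if (inherits(x, "service_area_ledger")) {
    p <- x$parcels
    ecotypes <- x$ecotypes
    weights <- x$guild_weights
  } else {
    p <- x
  }
  v <- compute_pwsa(compute_wsa(p, weights), ecotypes)
  # keep a stable row order and zero rows for absent ecotypes
  full <- tibble::tibble(ecotype = ecotypes$name)
  v <- dplyr::left_join(full, v, by = "ecotype")
  v$area_ha[is.na(v$area_ha)] <- 0
  v$wsa[is.na(v$wsa)] <- 0
  v$pwsa[is.na(v$pwsa)] <- 0
  attr(v, "total_area") <- sum(v$area_ha)
  attr(v, "total_wsa") <- sum(v$wsa)
  attr(v, "total_pwsa") <- sum(v$pwsa)
  class(v) <- c("hb_valuation", class(v))
  v
}

#' @export
print.hb_valuation <- function(x, ...) {
  cat("<valuation> per-ecotype rollup (ha / WSA / PWSA)\n")
  NextMethod()
  cat(sprintf("total: %.2f ha | WSA %.2f | PWSA %.2f\n",
              attr(x, "total_area"), attr(x, "total_wsa"),
              attr(x, "total_pwsa")))
  invisible(x)
}

#' Total PWSA of a valuation or ledger
#' @param x A valuation tibble or ledger.
#' @return A scalar, productivity-weighted hectares.
#' @export
total_pwsa <- function(x) {
  if (inherits(x, "service_area_ledger")) x <- valuation(x)
  attr(x, "total_pwsa")
}

#' Classify a suitability into the High / Med / Low quality classes
#'
#' The classes are reporting conveniences around the representative
#' suitabilities 0.75 (High), 0.50 (Med) and 0.25 (Low). Band edges sit at
#' the midpoints: High for s >= 0.625, Med for 0.375 <= s < 0.625, Low
#' below. Full-precision suitabilities drive all accounting; classes only
#' label reports.
#'
#' @param suitability Numeric vector in [0, 1].
#' @return Factor with levels High, Med, Low.
#' @export
classify_quality <- function(suitability) {
  if (any(is.na(suitability) | suitability < 0 | suitability > 1)) {
    stop("suitability outside [0, 1]")
  }
  cls <- ifelse(suitability >= 0.625, "High",
                ifelse(suitability >= 0.375, "Med", "Low"))
  factor(cls, levels = c("High", "Med", "Low"))
}

#' Representative suitability of a quality class
#' @param label Character vector of class labels (High / Med / Low).
#' @return Numeric vector of representative suitabilities.
#' @export
quality_class_value <- function(label) {
  v <- c(High = 0.75, Med = 0.50, Low = 0.25)
  unname(v[as.character(label)])
}

#' Hectares per quality class per ecotype
#'
#' Assigns every non-retired aquatic parcel to High / Med / Low by its
#' effective suitability and sums hectares per (ecotype, class); class
#' hectares of an ecotype sum to its area.
#'
#' @param p A [parcels()] inventory.
#' @param weights Optional guild weight table.
#' @return A tibble with columns `ecotype`, `class`, `area_ha`; cross-ecotype
#'   class totals as attribute `class_totals` (named numeric).
#' @export
quality_distribution <- function(p, weights = NULL) {
  p <- active_parcels(p)
  p <- p[p$ecotype != "terrestrial", , drop = FALSE]
  if (nrow(p) == 0) {
    out <- tibble::tibble(ecotype = character(), class = factor(levels = c("High", "Med", "Low")),
                          area_ha = numeric())
    attr(out, "class_totals") <- c(High = 0, Med = 0, Low = 0)
    return(out)
  }
  s <- effective_suitabilities(p, weights)
  out <- tibble::tibble(ecotype = p$ecotype, class = classify_quality(s),
                        area_ha = p$area_ha) |>
    dplyr::group_by(ecotype, class, .drop = FALSE) |>
    dplyr::summarise(area_ha = sum(area_ha), .groups = "drop")
  tot <- tapply(out$area_ha, out$class, sum, default = 0)
  attr(out, "class_totals") <- c(High = unname(tot["High"]),
                                 Med = unname(tot["Med"]),
                                 Low = unname(tot["Low"]))
  out
}
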