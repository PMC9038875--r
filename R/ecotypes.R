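#' Ecotype labels recognised by the ledger
#'
#' Five aquatic mesoscale ecotypes plus `terrestrial`. Terrestrial land is a
#' first-class ecotype with a potential productivity index (PPI) of zero, so
#' that land-to-water conversions are ordinary ecotype changes that conserve
#' area.
#'
#' @return Character vector of the six ecotype labels.
#' @export
ecotype_labels <- function() {
  c("terrestrial", "rivermouth", "wetland", "embayment", "open_coast",
    "offshore")
}

aquatic_labels <- function() setdiff(ecotype_labels(), "terrestrial")

#' Build an ecotype table
#'
#' An ecotype table maps each ecotype label to its potential productivity
#' index (PPI), the dimensionless exchange rate expressing the relative
#' maximum ongoing productivity of the ecotype. PPI must be non-negative and
#' names must be unique.
#'
#' @param name Character vector of ecotype labels.
#' @param ppi Numeric vector of non-negative PPI values, one per label.
#' @param description Optional character vector of free-text notes.
#' @return A tibble with columns `name`, `ppi`, `description`.
#' @seealso [default_ecotypes()] for the packaged nearshore defaults.
#' @export
ecotype_table <- function(name, ppi, description = NA_character_) {
  stopifnot(is.character(name), is.numeric(ppi), length(name) == length(ppi))
  tibble::tibble(name = name, ppi = as.numeric(ppi),
                 description = rep_len(as.character(description), length(name)))
}

#' Default ecotype/PPI table for a Great Lakes nearshore service area
#'
#' Rivermouth 1.5, wetland 2.0, embayment 1.0, open coast 0.5, offshore 0.25,
#' terrestrial 0 (land carries no aquatic value but is tracked so that
#' conversions conserve hectares).
#'
#' @return An ecotype table tibble.
#' @export
default_ecotypes <- function() {
  ecotype_table(
    name = c("terrestrial", "rivermouth", "wetland", "embayment",
             "open_coast", "offshore"),
    ppi = c(0, 1.5, 2.0, 1.0, 0.5, 0.25),
    description = c(
      "land above the high-water datum; zero aquatic suitability",
      "river and creek mouths",
      "coastal wetland",
      "protected embayment (<5 km fetch)",
      "open coast, <=30 m depth or <5 km from shore",
      "offshore, >30 m depth or >5 km out"
    )
  )
}

#' Thermal guild and life-stage identifiers
#'
#' @return Character vectors of the three thermal guilds and three life
#'   stages used in guild-resolved suitabilities.
#' @export
guild_stage_keys <- function() {
  guilds <- c("cold", "cool", "warm")
  stages <- c("spawning", "nursery", "juv_ad")
  keys <- as.vector(outer(stages, guilds, function(s, g) paste(g, s, sep = ".")))
  list(guilds = guilds, stages = stages, keys = keys)
}

#' Build a guild weight table
#'
#' Percent weights over the nine (thermal guild, life stage) combinations for
#' each aquatic ecotype, used to collapse guild-resolved suitabilities into
#' one effective parcel suitability. Every weight must be non-negative and
#' each ecotype column must sum to 100 percent.
#'
#' @param weights A 9 x k numeric matrix; rownames are `<guild>.<stage>` keys
#'   (see [guild_stage_keys()]), colnames are aquatic ecotype labels.
#' @return The validated matrix with class `guild_weights`.
#' @export
guild_weight_table <- function(weights) {
  stopifnot(is.matrix(weights), is.numeric(weights))
  keys <- guild_stage_keys()$keys
  if (!setequal(rownames(weights), keys)) {
    stop("guild weight rows must be exactly the nine guild.stage keys")
  }
  weights <- weights[keys, , drop = FALSE]
  structure(weights, class = c("guild_weights", "matrix", "array"))
}

#' Default guild weight matrix
#'
#' Coldwater guilds weigh most in open-coast and offshore columns, warmwater
#' guilds in rivermouth, wetland and embayment columns, coolwater guilds are
#' intermediate everywhere. Each column sums to 100.
#'
#' @return A `guild_weights` matrix (9 guild-stage rows x 5 aquatic ecotypes).
#' @export
default_guild_weights <- function() {
  m <- matrix(
    c( # rivermouth, wetland, embayment, open_coast, offshore
       6,  4,  7, 22, 20,   # cold.spawning
       7,  4,  6, 20, 22,   # cold.nursery
       8,  2,  5, 18, 24,   # cold.juv_ad
      11, 11, 15,  8,  8,   # cool.spawning
      11, 10, 17, 12, 12,   # cool.nursery
      11,  9, 17, 10, 10,   # cool.juv_ad
      15, 19, 11,  2,  1,   # warm.spawning
      16, 22, 11,  4,  1,   # warm.nursery
      15, 19, 11,  4,  2    # warm.juv_ad
    ),
    nrow = 9, byrow = TRUE,
    dimnames = list(guild_stage_keys()$keys, aquatic_labels())
  )
  guild_weight_table(m)
}

validate_guild_weights <- function(weights, tol = 1e-9) {
  bad <- character(0)
  if (any(weights < 0)) {
    bad <- c(bad, "guild_weights: negative weight present")
  }
  sums <- colSums(weights)
  off <- names(sums)[abs(sums - 100) > tol]
  if (length(off)) {
    bad <- c(bad, sprintf(
      "guild_weights: column '%s' sums to %s, not 100", off,
      format(sums[off])))
  }
  bad
}
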