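#' Aggregate per-meal recall entries into daily recall events
#'
#' Household dietary recalls are sometimes recorded meal by meal. The model
#' works at the resolution of 24-h recall events, so meals falling on the same
#' calendar day are collapsed: the day counts as a consumption event if any
#' meal that day contained wild meat, and the daily quantity is the sum of the
#' meal quantities. Records with a negative quantity are rejected and listed
#' in the `rejected` attribute of the result.
#'
#' @param meals data.frame with columns `household_id`, `day` (calendar day,
#'   any orderable type), `consumed` (0/1 flag per meal) and optionally
#'   `quantity_kg` (kg of undressed wild meat in that meal; `NA` allowed).
#' @return data.frame with one row per household-day: `household_id`, `day`,
#'   `consumed` (0/1), `quantity_kg` (sum over meals; `NA` if no meal reported
#'   a quantity). Attribute `rejected` holds the rows dropped for negative
#'   quantities.
#' @export
aggregate_within_day <- function(meals) {
  stopifnot(is.data.frame(meals),
            all(c("household_id", "day", "consumed") %in% names(meals)))
  if (is.null(meals$quantity_kg)) meals$quantity_kg <- NA_real_
  bad <- !is.na(meals$quantity_kg) & meals$quantity_kg < 0
  rejected <- meals[bad, , drop = FALSE]
  if (any(bad)) {
    warning(sprintf("%d meal record(s) with negative quantity rejected",
                    sum(bad)))
    meals <- meals[!bad, , drop = FALSE]
  }
  key <- interaction(meals$household_id, meals$day, drop = TRUE)
  sum_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  out <- data.frame(
    household_id = tapply(meals$household_id, key, `[`, 1),
    day          = tapply(meals$day, key, `[`, 1),
    consumed     = as.integer(tapply(meals$consumed, key, max) > 0),
    quantity_kg  = as.numeric(tapply(meals$quantity_kg, key, sum_na)),
    row.names    = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(out$household_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Frequency of consumption from recall events or a reported category
#'
#' The frequency of consumption is the proportion of monitored days on which a
#' household consumed wild meat. It is computed either from repeated recalls
#' (`events / monitored_days`, requiring at least two monitored days) or from
#' a reported category: `daily` = 1, `weekly` = 52/365, `monthly` = 12/365,
#' `yearly` = 1/365.
#'
#' @param events integer vector, number of consumption events.
#' @param monitored_days integer vector, total days monitored (>= 2).
#' @param category optional character vector; when given it overrides the
#'   count-based computation ("daily", "weekly", "monthly", "yearly").
#' @return numeric vector of frequencies in \[0, 1\].
#' @export
compute_frequency <- function(events = NULL, monitored_days = NULL,
                              category = NULL) {
  if (!is.null(category)) {
    lut <- c(daily = 1, weekly = 52 / 365, monthly = 12 / 365,
             yearly = 1 / 365)
    bad <- !category %in% names(lut)
    if (any(bad))
      stop("unknown frequency category: ",
           paste(unique(category[bad]), collapse = ", "))
    return(unname(lut[category]))
  }
  stopifnot(!is.null(events), !is.null(monitored_days))
  if (any(monitored_days < 2))
    stop("frequency from repeated recalls requires monitored_days >= 2")
  if (any(events < 0) || any(events > monitored_days))
    stop("events must lie in [0, monitored_days]")
  events / monitored_days
}

#' Standardize a cumulative recall quantity to kg per day
#'
#' Quantities reported over recall periods longer than 24 h are divided by the
#' recall duration so that all quantity records are daily.
#'
#' @param total_kg kg of undressed meat reported over the recall (>= 0).
#' @param recall_days recall duration in days (>= 1).
#' @return kg per day.
#' @export
standardize_daily_quantity <- function(total_kg, recall_days) {
  if (any(recall_days < 1)) stop("recall_days must be >= 1")
  if (any(total_kg < 0)) stop("total_kg must be >= 0")
  total_kg / recall_days
}

# fractions of a whole carcass used when quantities come in local units
.unit_fractions <- c(entire = 1, half = 0.5, quarter = 0.25, gigot = 0.25)

#' Convert local measurement units to kg
#'
#' Quantities reported in local units ("entire", "half", "quarter", "gigot",
#' or unit labels with a direct kg conversion such as "piece" or "pile") are
#' converted to kg. Carcass fractions multiply the species whole-body mass
#' from the conversion table; other unit labels are looked up directly.
#' Records whose unit (or species) cannot be resolved are flagged, excluded
#' and returned in the `flagged` attribute.
#'
#' @param unit_records data.frame with columns `unit` (label), `count`
#'   (number of units) and `species` (used for carcass fractions; may be `NA`
#'   for direct units).
#' @param table named numeric vector: kg per unit for direct unit labels and
#'   whole-body kg for species names. All values must be > 0.
#' @return numeric vector of kg, `NA` for flagged records; attribute
#'   `flagged` is a logical vector marking unresolvable records.
#' @export
convert_local_units <- function(unit_records, table) {
  stopifnot(all(table > 0))
  n <- nrow(unit_records)
  kg <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    u <- unit_records$unit[i]
    if (u %in% names(.unit_fractions)) {
      sp <- unit_records$species[i]
      if (is.na(sp) || !sp %in% names(table)) { flagged[i] <- TRUE; next }
      kg[i] <- unit_records$count[i] * .unit_fractions[[u]] * table[[sp]]
    } else if (u %in% names(table)) {
      kg[i] <- unit_records$count[i] * table[[u]]
    } else {
      flagged[i] <- TRUE
    }
  }
  if (any(flagged))
    message(sum(flagged), " unit record(s) flagged: unresolvable unit")
  attr(kg, "flagged") <- flagged
  kg
}

#' Adult male equivalents (AME) of a household
#'
#' Household size rescaled by age/sex energy multipliers so that per-capita
#' quantities are comparable across households: adult males 1, adult females
#' 0.86, children 10-15 y 0.96, 6-10 y 0.85, 0-5 y 0.52. Children of
#' unspecified age use 0.78 (the mean of the three child multipliers) and
#' adults of unspecified sex 0.93 (the mean of the two adult multipliers).
#' A household with all counts zero has unknown composition and returns `NA`
#' (to be imputed by the model), not 0.
#'
#' @param n_adult_male,n_adult_female,n_child_10_15,n_child_6_10,n_child_0_5,n_child_unspecified,n_adult_unspecified
#'   non-negative counts (vectorized).
#' @return numeric AME, `NA` where every count is zero.
#' @export
compute_ame <- function(n_adult_male = 0, n_adult_female = 0,
                        n_child_10_15 = 0, n_child_6_10 = 0, n_child_0_5 = 0,
                        n_child_unspecified = 0, n_adult_unspecified = 0) {
  counts <- cbind(n_adult_male, n_adult_female, n_child_10_15, n_child_6_10,
                  n_child_0_5, n_child_unspecified, n_adult_unspecified)
  if (any(counts < 0)) stop("counts must be >= 0")
  w <- c(1, 0.86, 0.96, 0.85, 0.52, 0.78, 0.93)
  ame <- as.numeric(counts %*% w)
  ame[rowSums(counts) == 0] <- NA_real_
  ame
}

#' Pairwise distance matrix between survey locations
#'
#' Great-circle (haversine, mean earth radius 6371 km) distances between all
#' pairs of locations, in km. Set `method = "euclidean"` for planar distances
#' when coordinates are already projected (same units as the coordinates).
#' Duplicate coordinates are allowed; the resulting off-diagonal zeros are
#' reported via a message.
#'
#' @param locations data.frame with columns `lon` and `lat` (decimal degrees)
#'   and optionally `location_id` used for dimnames.
#' @param method "haversine" (default) or "euclidean".
#' @return symmetric hollow matrix of distances (km for haversine).
#' @export
build_distance_matrix <- function(locations,
                                  method = c("haversine", "euclidean")) {
  method <- match.arg(method)
  stopifnot(nrow(locations) >= 2,
            all(c("lon", "lat") %in% names(locations)))
  xy <- as.matrix(locations[, c("lon", "lat")])
  if (method == "haversine") {
    D <- geosphere::distm(xy, fun = geosphere::distHaversine) / 1000
    # distm uses the WGS84 equatorial radius by default; rescale to the
    # mean earth radius so 1 degree of latitude is ~111.195 km
    D <- D * 6371 / 6378.137
  } else {
    D <- as.matrix(stats::dist(xy))
  }
  dup <- D[upper.tri(D)] == 0
  if (any(dup))
    message(sum(dup), " location pair(s) share identical coordinates")
  ids <- if (!is.null(locations$location_id)) locations$location_id else
    seq_len(nrow(locations))
  dimnames(D) <- list(ids, ids)
  D
}
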