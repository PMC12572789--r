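## Exposure keys -------------------------------------------------------------
## Exposures are indexed by a flat key set: "UPF", one "category:<name>" key
## per MUP category, and one key per specific marker. Categories and markers
## may share names (e.g. the flavour marker inside the flavour category), so
## category keys carry an explicit prefix.

#' Exposure keys of a lexicon
#' @param lexicon a \code{mup_lexicon}.
#' @return character vector: "UPF", "category:<name>" per category, then the
#'   specific marker names.
#' @export
exposure_keys <- function(lexicon = default_lexicon()) {
  c("UPF", paste0("category:", lexicon$categories), lexicon$marker_names)
}

#' Specific-marker keys (excludes UPF and category aggregates)
#' @param lexicon a \code{mup_lexicon}.
#' @export
specific_marker_keys <- function(lexicon = default_lexicon()) {
  lexicon$marker_names
}

## Per-product presence matrix over the full key set
presence_by_key <- function(texts, lexicon) {
  hits <- scan_ingredients_matrix(texts, lexicon)
  cats <- vapply(lexicon$categories, function(cc) {
    member <- lexicon$category_of == cc
    if (sum(member) == 1L) hits[, member] else rowSums(hits[, member, drop = FALSE]) > 0
  }, logical(length(texts)))
  if (length(texts) == 1L) cats <- matrix(cats, nrow = 1L,
                                          dimnames = list(NULL, lexicon$categories))
  upf <- rowSums(hits) > 0
  out <- cbind(UPF = upf, cats, hits)
  colnames(out) <- exposure_keys(lexicon)
  out
}

#' Resolve a product's portion to grams
#'
#' Portions reported in grams are used as-is; millilitres are converted with
#' an item-specific specific gravity; any other portion description (e.g.
#' "Mug/Cup") falls back to a configured per-item standard portion standing
#' in for packaging / standard-portion lookups.
#'
#' @param value numeric portion value(s).
#' @param unit character: "g", "ml" (case-insensitive), or anything else for
#'   the fallback rule.
#' @param item_id item identifier(s), used to look up gravity/fallback.
#' @param gravity named numeric vector mapping item_id to g/mL (default
#'   density 1.0 applies to items not listed).
#' @param fallback_g named numeric vector (or scalar) of standard portions in
#'   grams for non-g/mL portion descriptions.
#' @return numeric grams, same length as \code{value}.
#' @export
resolve_portion <- function(value, unit, item_id = NULL,
                            gravity = numeric(0), fallback_g = numeric(0)) {
  n <- max(length(value), length(unit))
  value <- rep_len(as.numeric(value), n)
  unit <- tolower(rep_len(as.character(unit), n))
  item_id <- if (is.null(item_id)) rep_len(NA_character_, n) else
    rep_len(as.character(item_id), n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- if (unit[i] == "g") {
      value[i]
    } else if (unit[i] %in% c("ml", "mL")) {
      g <- if (item_id[i] %in% names(gravity)) gravity[[item_id[i]]] else {
        if (length(gravity) && !is.null(attr(gravity, "strict")) &&
            isTRUE(attr(gravity, "strict")))
          stop("no specific gravity configured for item ", item_id[i])
        1.0
      }
      value[i] * g
    } else {
      fb <- if (item_id[i] %in% names(fallback_g)) fallback_g[[item_id[i]]]
      else if (length(fallback_g) == 1L && is.null(names(fallback_g))) fallback_g
      else stop("no fallback portion configured for item ", item_id[i],
                " (portion description '", unit[i], "')")
      fb
    }
  }
  if (any(!is.finite(out) | out <= 0))
    stop("nonpositive or non-finite resolved portion for item(s): ",
         paste(unique(item_id[!is.finite(out) | out <= 0]), collapse = ", "))
  out
}

#' Marker Likelihood Index for one WebQ item
#'
#' The MLI of an exposure key is the fraction of the item's researched
#' commercial products whose ingredient list carries that key: a product
#' carries a category iff it carries any member marker, and counts as UPF iff
#' it carries any marker at all. Items with fewer products than
#' \code{max_products} use all available products as the denominator.
#'
#' @param products data.frame for one item with columns
#'   \code{ingredients_text}, \code{portion_g}, \code{energy_kj_100g}
#'   (products in catalogue order; truncation keeps the first ones).
#' @param lexicon a \code{mup_lexicon}.
#' @param max_products use only the first \code{max_products} products
#'   (10 by default; 8/6/4 serve the truncated-MLI sensitivity analysis).
#' @return list with \code{mli} (named numeric over \code{exposure_keys}),
#'   \code{mean_portion_g}, \code{mean_energy_kj_100g}, \code{n_products}.
#' @export
compute_mli <- function(products, lexicon = default_lexicon(), max_products = 10L) {
  if (is.null(products) || nrow(products) == 0L) stop("no products for item")
  stopifnot(max_products >= 1L)
  keep <- seq_len(min(nrow(products), max_products))
  products <- products[keep, , drop = FALSE]
  pres <- presence_by_key(products$ingredients_text, lexicon)
  list(
    mli = colMeans(pres),
    mean_portion_g = mean(products$portion_g),
    mean_energy_kj_100g = mean(products$energy_kj_100g),
    n_products = nrow(products)
  )
}

#' Build the full MLI table from a product catalogue
#'
#' @param catalogue data.frame with columns \code{item_id},
#'   \code{ingredients_text}, and either \code{portion_g} or the raw pair
#'   \code{portion_value}/\code{portion_unit} (resolved via
#'   \code{\link{resolve_portion}}), plus \code{energy_kj_100g}.
#' @param lexicon a \code{mup_lexicon}.
#' @param max_products first-k product truncation (default 10).
#' @param gravity,fallback_g passed to \code{\link{resolve_portion}} when raw
#'   portions are supplied.
#' @return object of class \code{mli_table}: \code{mli} matrix (items x
#'   exposure keys) and \code{items} data.frame (item_id, mean_portion_g,
#'   mean_energy_kj_100g, n_products).
#' @export
build_mli_table <- function(catalogue, lexicon = default_lexicon(),
                            max_products = 10L,
                            gravity = numeric(0), fallback_g = numeric(0)) {
  stopifnot(is.data.frame(catalogue), nrow(catalogue) > 0L)
  if (!"portion_g" %in% names(catalogue)) {
    catalogue$portion_g <- resolve_portion(catalogue$portion_value,
                                           catalogue$portion_unit,
                                           catalogue$item_id,
                                           gravity, fallback_g)
  }
  ids <- unique(catalogue$item_id)
  keys <- exposure_keys(lexicon)
  mli <- matrix(NA_real_, length(ids), length(keys),
                dimnames = list(as.character(ids), keys))
  meta <- data.frame(item_id = as.character(ids),
                     mean_portion_g = NA_real_,
                     mean_energy_kj_100g = NA_real_,
                     n_products = NA_integer_,
                     stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    one <- compute_mli(catalogue[catalogue$item_id == ids[k], , drop = FALSE],
                       lexicon, max_products)
    mli[k, ] <- one$mli
    meta$mean_portion_g[k] <- one$mean_portion_g
    meta$mean_energy_kj_100g[k] <- one$mean_energy_kj_100g
    meta$n_products[k] <- one$n_products
  }
  structure(list(mli = mli, items = meta, lexicon_keys = keys,
                 max_products = max_products),
            class = "mli_table")
}

#' @export
print.mli_table <- function(x, ...) {
  cat("MLI table:", nrow(x$mli), "items x", ncol(x$mli), "exposure keys",
      sprintf("(first %d products per item)\n", x$max_products))
  invisible(x)
}

#' Grams of an item's portion attributed to a marker
#'
#' @param portion_g portion size in grams (> 0).
#' @param mli Marker Likelihood Index in [0, 1].
#' @return \code{portion_g * mli}, the grams regarded as carrying the marker.
#' @examples
#' item_marker_grams(50, 0.6)  # 30 g of a 50 g chocolate bar counted as flavoured
#' @export
item_marker_grams <- function(portion_g, mli) {
  stopifnot(all(portion_g > 0), all(mli >= 0 & mli <= 1))
  portion_g * mli
}

#' Gram and energy totals for one dietary recall
#'
#' @param recall data.frame with columns \code{item_id}, \code{n_portions}
#'   for one completed 24-h recall.
#' @param mli_table an \code{\link{build_mli_table}} result.
#' @return list(total_food_g, marker_g = named vector over exposure keys,
#'   total_energy_kj).
#' @export
recall_exposure <- function(recall, mli_table) {
  keys <- colnames(mli_table$mli)
  if (is.null(recall) || nrow(recall) == 0L) {
    return(list(total_food_g = 0,
                marker_g = stats::setNames(numeric(length(keys)), keys),
                total_energy_kj = 0))
  }
  idx <- match(as.character(recall$item_id), mli_table$items$item_id)
  if (anyNA(idx))
    stop("recall refers to unknown item id(s): ",
         paste(unique(recall$item_id[is.na(idx)]), collapse = ", "))
  stopifnot(all(recall$n_portions > 0))
  grams <- recall$n_portions * mli_table$items$mean_portion_g[idx]
  energy <- grams * mli_table$items$mean_energy_kj_100g[idx] / 100
  list(total_food_g = sum(grams),
       marker_g = drop(crossprod(mli_table$mli[idx, , drop = FALSE], grams)),
       total_energy_kj = sum(energy))
}

#' Exposure profile (%TFI) for one participant
#'
#' Gram intakes are averaged across recalls (ratio of means), then each
#' exposure key's percentage of total food intake is
#' 100 * mean marker grams / mean total grams. Under \code{first_recall} only
#' recall 1 is used (first-recall sensitivity analysis).
#'
#' @param recalls data.frame with columns \code{recall_index},
#'   \code{item_id}, \code{n_portions} for one participant.
#' @param mli_table an \code{mli_table}.
#' @param mode "mean_over_recalls" (default) or "first_recall".
#' @return list(tfi = named vector of %TFI per key, cumulative_specific_mup,
#'   total_food_g, total_energy_kj, n_recalls).
#' @export
build_profile <- function(recalls, mli_table,
                          mode = c("mean_over_recalls", "first_recall")) {
  mode <- match.arg(mode)
  stopifnot(nrow(recalls) >= 1L)
  if (mode == "first_recall") {
    first <- min(recalls$recall_index)
    recalls <- recalls[recalls$recall_index == first, , drop = FALSE]
  }
  by_recall <- lapply(split(recalls, recalls$recall_index),
                      recall_exposure, mli_table = mli_table)
  total_g <- mean(vapply(by_recall, `[[`, numeric(1), "total_food_g"))
  if (total_g <= 0) stop("zero total intake")
  marker_g <- Reduce(`+`, lapply(by_recall, `[[`, "marker_g")) / length(by_recall)
  energy <- mean(vapply(by_recall, `[[`, numeric(1), "total_energy_kj"))
  tfi <- 100 * marker_g / total_g
  list(tfi = tfi,
       cumulative_specific_mup = cumulative_intake(tfi),
       total_food_g = total_g,
       total_energy_kj = energy,
       n_recalls = length(by_recall))
}

#' Cumulative specific-MUP intake
#'
#' Sum of the %TFI values of the specific markers only (category aggregates
#' and the UPF key are excluded). The unit is a %TFI-sum and can exceed 100.
#'
#' @param tfi named numeric vector of %TFI values over exposure keys, or the
#'   list returned by \code{\link{build_profile}}.
#' @return numeric scalar.
#' @examples
#' cumulative_intake(c("flavour" = 3, "acesulfame" = 2, "emulsifier" = 5))
#' @export
cumulative_intake <- function(tfi) {
  if (is.list(tfi) && !is.null(tfi$tfi)) tfi <- tfi$tfi
  specific <- setdiff(names(tfi), c("UPF", grep("^category:", names(tfi), value = TRUE)))
  sum(tfi[specific])
}

#' Exposure profiles for a whole cohort
#'
#' @param recalls data.frame with columns \code{participant_id},
#'   \code{recall_index}, \code{item_id}, \code{n_portions}.
#' @param mli_table an \code{mli_table}.
#' @param mode see \code{\link{build_profile}}.
#' @return object of class \code{exposure_profiles}: \code{participant_id},
#'   \code{tfi} matrix (participants x exposure keys), \code{cumulative},
#'   \code{total_food_g}, \code{total_energy_kj}, \code{n_recalls}.
#' @export
build_profiles <- function(recalls, mli_table,
                           mode = c("mean_over_recalls", "first_recall")) {
  mode <- match.arg(mode)
  parts <- split(recalls, recalls$participant_id)
  ids <- names(parts)
  keys <- colnames(mli_table$mli)
  tfi <- matrix(NA_real_, length(ids), length(keys),
                dimnames = list(ids, keys))
  total_g <- total_e <- cum <- numeric(length(ids))
  nrec <- integer(length(ids))
  for (i in seq_along(parts)) {
    p <- build_profile(parts[[i]], mli_table, mode)
    tfi[i, ] <- p$tfi
    total_g[i] <- p$total_food_g
    total_e[i] <- p$total_energy_kj
    nrec[i] <- p$n_recalls
    cum[i] <- cumulative_intake(p$tfi)
  }
  structure(list(participant_id = ids, tfi = tfi, cumulative = cum,
                 total_food_g = total_g, total_energy_kj = total_e,
                 n_recalls = nrec),
            class = "exposure_profiles")
}

#' @export
print.exposure_profiles <- function(x, ...) {
  cat("Exposure profiles:", length(x$participant_id), "participants,",
      ncol(x$tfi), "exposure keys\n")
  cat("  mean UPF intake:", round(mean(x$tfi[, "UPF"]), 2), "%TFI\n")
  invisible(x)
}

#' Write exposure profiles to CSV (one row per participant)
#' @param profiles an \code{exposure_profiles} object.
#' @param path output path.
#' @export
write_profiles_csv <- function(profiles, path) {
  df <- data.frame(participant_id = profiles$participant_id,
                   total_food_g = profiles$total_food_g,
                   total_energy_kj = profiles$total_energy_kj,
                   n_recalls = profiles$n_recalls,
                   cumulative_specific_mup = profiles$cumulative,
                   check.names = FALSE)
  tfi <- as.data.frame(profiles$tfi, check.names = FALSE)
  names(tfi) <- paste0("tfi:", names(tfi))
  utils::write.csv(cbind(df, tfi), path, row.names = FALSE)
}
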