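#' Tabulate outcome categories for one drug or class
#'
#' Counts case records over the five informative outcome categories
#' (death, with sequelae, not recovered, improved, recovered); outcomes
#' recorded as unknown or left blank are excluded from the denominator
#' and counted in \code{n_excluded_unknown}.
#'
#' @param records an \code{analysis_set}.
#' @param drug_or_class value of the \code{drug} column.
#' @return an \code{outcome_table}: list with \code{drug_or_class},
#'   named \code{counts} over the five categories, \code{denominator}
#'   and \code{n_excluded_unknown}.
#' @export
tabulate_outcomes <- function(records, drug_or_class) {
  stopifnot(is.data.frame(records))
  r <- records[records$drug == drug_or_class & records$is_case, , drop = FALSE]
  kept <- OUTCOME_CODES[1:5]
  oc <- r$outcome
  excluded <- is.na(oc) | oc == "unknown" | oc == ""
  counts <- table(factor(oc[!excluded], levels = kept))
  out <- structure(list(drug_or_class = drug_or_class,
                        counts = setNames(as.integer(counts), kept),
                        denominator = sum(counts),
                        n_excluded_unknown = sum(excluded)),
                   class = "outcome_table")
  if (out$denominator == 0L && nrow(r) > 0L)
    warning("all outcomes unknown/blank for ", sQuote(drug_or_class),
            call. = FALSE)
  out
}

#' Outcome table from explicit counts
#'
#' @param counts named integer vector over \code{death},
#'   \code{with_sequelae}, \code{not_recovered}, \code{improved},
#'   \code{recovered} (missing categories default to 0).
#' @param drug_or_class label.
#' @param n_excluded_unknown optional excluded-record count.
#' @return an \code{outcome_table}.
#' @export
outcome_table <- function(counts, drug_or_class = "",
                          n_excluded_unknown = 0L) {
  kept <- OUTCOME_CODES[1:5]
  bad <- setdiff(names(counts), kept)
  if (length(bad))
    stop("unknown outcome category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  full <- setNames(rep(0L, 5L), kept)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("negative outcome count", call. = FALSE)
  structure(list(drug_or_class = drug_or_class, counts = full,
                 denominator = sum(full),
                 n_excluded_unknown = as.integer(n_excluded_unknown)),
            class = "outcome_table")
}

#' Combined favourable / unfavourable outcome frequencies
#'
#' Favourable = (recovered + improved) / denominator; unfavourable =
#' (death + with sequelae + not recovered) / denominator. The two
#' fractions sum to 1 exactly; rounding to the customary one decimal
#' happens only at presentation.
#'
#' @param table an \code{outcome_table}.
#' @return list with \code{favourable_frac}, \code{unfavourable_frac},
#'   \code{favourable_n}, \code{unfavourable_n}, \code{denominator}.
#' @export
combined_frequencies <- function(table) {
  stopifnot(inherits(table, "outcome_table"))
  if (table$denominator < 1)
    stop("zero denominator: no informative outcomes", call. = FALSE)
  fav <- table$counts[["recovered"]] + table$counts[["improved"]]
  unf <- table$counts[["death"]] + table$counts[["with_sequelae"]] +
    table$counts[["not_recovered"]]
  list(favourable_frac = fav / table$denominator,
       unfavourable_frac = unf / table$denominator,
       favourable_n = fav, unfavourable_n = unf,
       denominator = table$denominator)
}

#' Mosaic-plot geometry for a set of outcome tables
#'
#' Column widths are proportional to each table's informative
#' denominator; within a column the vertical segments are the category
#' proportions (summing to 1). The output is a plain data frame from
#' which a mosaic plot can be drawn with any graphics layer.
#'
#' @param tables list of \code{outcome_table} objects.
#' @return data frame with columns \code{drug_or_class},
#'   \code{category}, \code{count}, \code{proportion}, \code{width}.
#' @export
mosaic_data <- function(tables) {
  stopifnot(length(tables) >= 1)
  dens <- vapply(tables, function(t) t$denominator, numeric(1))
  total <- sum(dens)
  if (total == 0) stop("all tables empty", call. = FALSE)
  rows <- lapply(tables, function(t) {
    prop <- if (t$denominator > 0) t$counts / t$denominator else
      rep(NA_real_, 5L)
    data.frame(drug_or_class = t$drug_or_class,
               category = names(t$counts),
               count = unname(t$counts),
               proportion = unname(prop),
               width = t$denominator / total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
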