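#' Build per-patient power/rating summaries
#'
#' Averages significant-cluster mean power across a patient's contacts in a
#' region, and expresses valence ratings relative to the neutral condition.
#' Patients with a missing rating for a required condition are dropped, with
#' a message reporting the count.
#'
#' @param cluster_means named numeric: cluster-mean dB per contact; names are
#'   contact ids.
#' @param ratings data.frame with columns `patient`, `condition`, `rating`
#'   (0-100 scale; one row per patient x condition, NA or absent allowed).
#' @param contact_map data.frame with columns `contact`, `patient`.
#' @param conditions non-neutral conditions to summarise.
#' @param neutral label of the reference condition.
#' @return data.frame of class `patient_summary` with columns `patient`,
#'   `condition`, `power_db` (contact-averaged) and `rating_rel`
#'   (condition minus neutral rating).
#' @export
build_patient_summaries <- function(cluster_means, ratings, contact_map,
                                    conditions = c("positive", "negative"),
                                    neutral = "neutral") {
  stopifnot(all(c("contact", "patient") %in% names(contact_map)),
            all(c("patient", "condition", "rating") %in% names(ratings)))
  contacts <- names(cluster_means)
  if (is.null(contacts)) stop("cluster_means must be named by contact")
  pat <- contact_map$patient[match(contacts, contact_map$contact)]
  if (anyNA(pat))
    stop("contact(s) without patient mapping: ",
         paste(contacts[is.na(pat)], collapse = ", "))
  pow <- tapply(cluster_means, pat, mean)
  get_rating <- function(p, cn) {
    r <- ratings$rating[ratings$patient == p & ratings$condition == cn]
    if (length(r) == 0 || is.na(r[1])) NA_real_ else r[1]
  }
  rows <- list(); dropped <- 0L
  for (p in names(pow)) {
    neu <- get_rating(p, neutral)
    for (cn in conditions) {
      rc <- get_rating(p, cn)
      if (is.na(neu) || is.na(rc)) {
        dropped <- dropped + 1L
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        patient = p, condition = cn, power_db = unname(pow[p]),
        rating_rel = rc - neu, stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0)
    message(dropped, " patient x condition row(s) dropped for missing ratings")
  out <- do.call(rbind, rows)
  class(out) <- c("patient_summary", class(out))
  out
}

#' Correlate cluster band power with valence ratings
#'
#' Pearson correlation over (power_db, rating_rel) pairs, pooling the
#' positive and negative condition rows (two rows per patient), with a
#' two-tailed p-value.
#'
#' @param summaries a data.frame from [build_patient_summaries()], or any
#'   data.frame with `power_db` and `rating_rel` columns.
#' @return list with `r`, `p`, `n` and `degenerate` (TRUE if either variable
#'   has zero variance, in which case r and p are NA).
#' @export
correlate_with_ratings <- function(summaries) {
  x <- summaries$power_db; y <- summaries$rating_rel
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = n, degenerate = FALSE)
}
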