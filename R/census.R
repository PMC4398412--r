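# Census-style demographic tables: loading, projection into the (x, y)
# plane, classification against a transition stripe, and synthetic fixture
# generation. The package deliberately bundles no historical census values;
# users supply their own tables in the schema below (or via column aliases).

.census_required <- c("territory", "n_white", "n_free_colored", "n_slave")
.census_optional <- c("subdivision", "year", "creole_observed")

#' Read a census-style demographic table
#'
#' Expects columns \code{territory}, \code{n_white} (Free Whites /
#' Europeans), \code{n_free_colored} (Mulattos) and \code{n_slave} (Bozals),
#' plus optional \code{subdivision} (county/parish), \code{year} and
#' \code{creole_observed} (logical: did a creole historically emerge
#' there?). Other column names can be mapped onto the schema through
#' \code{aliases}. Rows with missing or negative counts are rejected with
#' row-level diagnostics rather than failing the whole file.
#'
#' @param path CSV file path.
#' @param aliases Optional named character vector mapping file column names
#'   to schema names, e.g. \code{c(free_blacks = "n_free_colored")}.
#' @return Data frame of validated records; rejected rows (if any) are
#'   reported in a warning and kept in the \code{"rejected"} attribute.
#' @export
read_census_csv <- function(path, aliases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0) stop("empty input: ", path)
  if (!is.null(aliases)) {
    hit <- names(df) %in% names(aliases)
    names(df)[hit] <- unname(aliases[names(df)[hit]])
  }
  missing_cols <- setdiff(.census_required, names(df))
  if (length(missing_cols))
    stop("schema error: missing required column(s) ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(.census_optional, names(df)))
    df[[col]] <- switch(col, subdivision = NA_character_,
                        year = NA_integer_, creole_observed = NA)
  df <- df[c(.census_required, .census_optional)]
  for (col in c("n_white", "n_free_colored", "n_slave"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  if (!is.logical(df$creole_observed))
    df$creole_observed <- vapply(df$creole_observed, function(v) {
      if (is.na(v)) return(NA)
      v <- tolower(as.character(v))
      if (v %in% c("true", "t", "yes", "1")) TRUE
      else if (v %in% c("false", "f", "no", "0")) FALSE
      else NA
    }, logical(1))
  counts <- df[c("n_white", "n_free_colored", "n_slave")]
  bad <- apply(counts, 1, function(r) any(is.na(r)) || any(r < 0) ||
                 any(r != round(r)))
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with missing/negative/non-integer counts: rows %s",
                    sum(bad), paste(which(bad), collapse = ", ")))
    rejected <- df[bad, , drop = FALSE]
    df <- df[!bad, , drop = FALSE]
    attr(df, "rejected") <- rejected
  }
  rownames(df) <- NULL
  df
}

#' Project census records onto the demographic plane
#'
#' Computes, for each record, \code{x = n_free_colored /
#' (n_free_colored + n_slave)} (Mulatto share of the Black population) and
#' \code{y = (n_free_colored + n_slave) / total} (Black share of the total
#' population). Both are ratios, so the projection is invariant under
#' rescaling all three counts. Records with zero Black population have no
#' defined \code{x}; a single such record is an error, and in a multi-row
#' table such rows yield \code{NA} with a warning.
#'
#' @param records Census data frame (as from \code{\link{read_census_csv}})
#'   or a single record as a list with the three count fields.
#' @return Data frame with columns \code{x}, \code{y}.
#' @examples
#' to_point(list(n_white = 100, n_free_colored = 50, n_slave = 850))
#' @export
to_point <- function(records) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  nb <- records$n_free_colored + records$n_slave
  tot <- records$n_white + nb
  if (any(is.na(nb)) || any(tot < 1, na.rm = TRUE))
    stop("records need non-missing counts and total population >= 1")
  undef <- nb == 0
  if (all(undef))
    stop("unclassifiable record: zero Black population, x undefined")
  if (any(undef))
    warning(sprintf("%d record(s) with zero Black population left NA",
                    sum(undef)))
  x <- ifelse(undef, NA_real_, records$n_free_colored / nb)
  y <- ifelse(undef, NA_real_, nb / tot)
  data.frame(x = x, y = y)
}

#' Classify demographic points against a transition stripe
#'
#' A point above the stripe's upper curve is predicted to develop a creole;
#' below the lower curve the European language is predicted to prevail;
#' points on or between the boundary curves are uncertain (the boundaries
#' are inclusive). The signed distance to the mid curve orders points by
#' how borderline they are.
#'
#' @param points Data frame with columns \code{x}, \code{y} (or a single
#'   \code{\link{demographic_point}}).
#' @param stripe A \code{transition_stripe}.
#' @return Data frame \code{x}, \code{y}, \code{verdict} (one of
#'   \code{"creole_predicted"}, \code{"no_creole_predicted"},
#'   \code{"uncertain"}) and \code{distance_to_mid_curve}.
#' @export
classify <- function(points, stripe) {
  if (inherits(points, "demographic_point"))
    points <- data.frame(x = points$x, y = points$y)
  if (nrow(stripe) == 0) stop("configuration error: empty stripe")
  bounds <- stripe_at(stripe, points$x)
  verdict <- ifelse(points$y > bounds$y_upper, "creole_predicted",
                    ifelse(points$y < bounds$y_lower, "no_creole_predicted",
                           "uncertain"))
  data.frame(x = points$x, y = points$y, verdict = verdict,
             distance_to_mid_curve = points$y - bounds$y_mid)
}

#' Classify a census table
#'
#' Convenience wrapper: projects each record with \code{\link{to_point}}
#' and classifies it against the stripe. Records with zero Black population
#' are skipped (verdict \code{NA}) with a warning.
#'
#' @param records Census data frame.
#' @param stripe A \code{transition_stripe}.
#' @return The input records with added columns \code{x}, \code{y},
#'   \code{verdict}, \code{distance_to_mid_curve}.
#' @export
classify_census <- function(records, stripe) {
  pts <- to_point(records)
  ok <- !is.na(pts$x)
  out <- cbind(records,
               data.frame(x = pts$x, y = pts$y,
                          verdict = NA_character_,
                          distance_to_mid_curve = NA_real_))
  if (any(ok)) {
    cl <- classify(pts[ok, , drop = FALSE], stripe)
    out$verdict[ok] <- cl$verdict
    out$distance_to_mid_curve[ok] <- cl$distance_to_mid_curve
  }
  out
}

#' Evaluate classifications against observed creole emergence
#'
#' Compares verdicts with the \code{creole_observed} labels. Records
#' classified \code{uncertain} are excluded from the accuracy denominator
#' and listed as borderline, ordered by absolute distance to the mid curve
#' (the demographic-plane notion of "close to the transition line").
#'
#' @param classified Output of \code{\link{classify_census}} (must retain
#'   \code{creole_observed}).
#' @return A list: \code{n_labeled}, \code{n_correct}, \code{n_incorrect},
#'   \code{n_uncertain}, \code{accuracy}, \code{confusion} (2x2 table over
#'   definite verdicts) and \code{borderline} (data frame).
#' @export
evaluate_predictions <- function(classified) {
  lab <- classified[!is.na(classified$creole_observed) &
                      !is.na(classified$verdict), , drop = FALSE]
  if (nrow(lab) == 0)
    stop("empty evaluation: no records with both a label and a verdict")
  definite <- lab$verdict != "uncertain"
  pred <- lab$verdict[definite] == "creole_predicted"
  obs <- lab$creole_observed[definite]
  correct <- pred == obs
  confusion <- table(predicted = factor(pred, c(FALSE, TRUE),
                                        c("no_creole", "creole")),
                     observed = factor(obs, c(FALSE, TRUE),
                                       c("no_creole", "creole")))
  borderline <- lab[lab$verdict == "uncertain", , drop = FALSE]
  borderline <- borderline[order(abs(borderline$distance_to_mid_curve)), ,
                           drop = FALSE]
  list(n_labeled = nrow(lab),
       n_correct = sum(correct),
       n_incorrect = sum(!correct),
       n_uncertain = sum(!definite),
       accuracy = if (any(definite)) mean(correct) else NA_real_,
       confusion = confusion,
       borderline = borderline)
}

#' Generate synthetic census fixtures on either side of a stripe
#'
#' Samples labelled records emulating the clustering of historical
#' territories: creole-like records at demographies at least \code{margin}
#' above the stripe's upper curve, non-creole-like ones at least
#' \code{margin} below its lower curve. Totals are drawn log-uniformly in
#' \code{1e2 .. 1e6} and integerized so that the round-trip through
#' \code{\link{to_point}} stays on the intended side. These are synthetic
#' fixtures, not historical data.
#'
#' @param n_creole_like,n_noncreole_like Number of records per side.
#' @param margin Minimum vertical clearance from the stripe, > 0.
#' @param stripe A \code{transition_stripe}.
#' @param seed Integer seed (same seed, same output).
#' @return Census data frame with \code{creole_observed} labels set.
#' @export
synthesize_census <- function(n_creole_like, n_noncreole_like, margin,
                              stripe, seed = 1L) {
  if (!is.numeric(margin) || margin <= 0) stop("'margin' must be > 0")
  ok <- stats::complete.cases(stripe[c("x", "y_lower", "y_upper")])
  if (!any(ok)) stop("stripe has no defined x values")
  xr <- range(stripe$x[ok])
  y_top <- 0.995; y_bot <- 0.01
  probe <- stripe_at(stripe, seq(xr[1], xr[2], length.out = 64))
  if (n_creole_like > 0 && all(probe$y_upper + margin >= y_top))
    stop("generation error: margin leaves no room above the stripe")
  if (n_noncreole_like > 0 && all(probe$y_lower - margin <= y_bot))
    stop("generation error: margin leaves no room below the stripe")

  draw_record <- function(i, creole) {
    for (try in 1:500) {
      x <- stats::runif(1, xr[1], xr[2])
      b <- stripe_at(stripe, x)
      y <- if (creole) {
        lo <- b$y_upper + margin
        if (lo >= y_top) next
        stats::runif(1, lo, y_top)
      } else {
        hi <- b$y_lower - margin
        if (hi <= y_bot) next
        stats::runif(1, y_bot, hi)
      }
      n_total <- round(10 ^ stats::runif(1, 2, 6))
      cnt <- tryCatch(point_to_counts(demographic_point(x, y), n_total),
                      error = function(e) NULL)
      if (is.null(cnt) || cnt[["n_m"]] + cnt[["n_b"]] == 0) next
      # verify the integerized record still falls on the intended side
      pt <- to_point(list(n_white = cnt[["n_eu"]],
                          n_free_colored = cnt[["n_m"]],
                          n_slave = cnt[["n_b"]]))
      # integer rounding can push x marginally outside the tabulated
      # range; nearest-endpoint lookup is exactly what is wanted here
      b2 <- suppressWarnings(stripe_at(stripe, pt$x))
      side_ok <- if (creole) pt$y > b2$y_upper else pt$y < b2$y_lower
      if (!side_ok) next
      return(data.frame(
        territory = sprintf("synthetic_%s_%02d",
                            if (creole) "creole" else "noncreole", i),
        n_white = cnt[["n_eu"]], n_free_colored = cnt[["n_m"]],
        n_slave = cnt[["n_b"]], subdivision = NA_character_,
        year = NA_integer_, creole_observed = creole))
    }
    stop("generation error: could not place a record with the given margin")
  }

  with_seed(seed, {
    rows <- c(lapply(seq_len(n_creole_like), draw_record, creole = TRUE),
              lapply(seq_len(n_noncreole_like), draw_record, creole = FALSE))
    df <- do.call(rbind, rows)
    df[c(.census_required, .census_optional)]
  })
}

#' Write a classification table as CSV
#'
#' @param classified Output of \code{\link{classify_census}}.
#' @param path Output file.
#' @param header Optional provenance comment lines (without the leading
#'   \code{#}).
#' @return \code{path}, invisibly.
#' @export
write_classifications <- function(classified, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# creolegame classifications",
               if (length(header)) paste("#", header)), con)
  utils::write.csv(classified, con, row.names = FALSE)
  invisible(path)
}
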