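# Questionnaire-derived exposure and symptom scales: stressful-life-event
# (SLE) counts split into behaviour-dependent and independent subscales,
# the log-transformed 28-item GHQ symptom score, the four-point PHQ
# recode, and proxy-case labelling from first-degree relatives.

#' Default item classification for a 12-item life-events list
#'
#' Items 1-5 are classed as independent of the respondent's own
#' behaviour (with item 5, pregnancy, flagged for removal from the
#' independent subscale), items 6-11 as potentially dependent on it, and
#' item 12 as excluded from both subscales. The classification is a
#' plain tibble so alternative instruments can be supplied.
#'
#' @return Tibble with columns `item` (1-based index), `class`
#'   (`"independent"`, `"dependent"` or `"excluded_from_subscales"`) and
#'   `pregnancy` (logical).
#' @export
default_sle_classes <- function() {
  tibble::tibble(
    item = 1:12,
    class = c(rep("independent", 5), rep("dependent", 6),
              "excluded_from_subscales"),
    pregnancy = c(rep(FALSE, 4), TRUE, rep(FALSE, 7))
  )
}

#' Score stressful life events into total, dependent and independent counts
#'
#' `tsle` counts every "yes" over all items; `dsle` counts "yes" among
#' behaviour-dependent items; `isle` counts "yes" among independent items
#' with the pregnancy item removed. Missing responses count as "no" (the
#' per-sample number of missing items is reported so callers can filter).
#'
#' @param responses A data frame of per-sample item responses: columns
#'   `fid`/`iid` (optional) plus one column per item, values in
#'   \{"yes","no",NA\} or \{1,0,NA\}.
#' @param item_classes Item classification tibble as returned by
#'   [default_sle_classes()]; must cover every item column.
#' @return Tibble with `fid`, `iid` (when present), `tsle`, `dsle`,
#'   `isle` and `n_missing`.
#' @examples
#' resp <- tibble::tibble(iid = "s1", i1 = "yes", i2 = "no", i3 = "yes",
#'                        i4 = "no", i5 = "no", i6 = "yes", i7 = "no",
#'                        i8 = "no", i9 = "no", i10 = "no", i11 = "no",
#'                        i12 = "no")
#' score_sle(resp)
#' @export
score_sle <- function(responses, item_classes = default_sle_classes()) {
  id_cols <- intersect(c("fid", "iid"), names(responses))
  item_cols <- setdiff(names(responses), id_cols)
  k <- length(item_cols)
  if (nrow(item_classes) < k) {
    stop("`item_classes` must cover all ", k, " item columns", call. = FALSE)
  }
  cls <- item_classes$class[seq_len(k)]
  preg <- item_classes$pregnancy[seq_len(k)]

  to_yes <- function(x) {
    if (is.numeric(x) || is.logical(x)) {
      bad <- !is.na(x) & !(x %in% c(0, 1))
      if (any(bad)) stop("numeric responses must be 0/1", call. = FALSE)
      return(!is.na(x) & x == 1)
    }
    x <- tolower(as.character(x))
    bad <- !is.na(x) & !(x %in% c("yes", "no"))
    if (any(bad)) {
      stop("unknown response code(s): ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    !is.na(x) & x == "yes"
  }

  yes <- vapply(responses[item_cols], to_yes, logical(nrow(responses)))
  if (is.null(dim(yes))) yes <- matrix(yes, nrow = nrow(responses))
  miss <- vapply(responses[item_cols], function(x) is.na(x),
                 logical(nrow(responses)))
  if (is.null(dim(miss))) miss <- matrix(miss, nrow = nrow(responses))

  out <- tibble::tibble(
    tsle = as.integer(rowSums(yes)),
    dsle = as.integer(rowSums(yes[, cls == "dependent", drop = FALSE])),
    isle = as.integer(rowSums(yes[, cls == "independent" & !preg, drop = FALSE])),
    n_missing = as.integer(rowSums(miss))
  )
  dplyr::bind_cols(responses[id_cols], out)
}

#' Log-transform a 28-item GHQ score
#'
#' Sums the 28 Likert-scored items (0-3 each under the default scoring)
#' and returns the natural log of (1 + sum); the +1 offset keeps a raw
#' sum of zero finite and the transform strictly monotone in the raw
#' sum. The binary GHQ scoring variant (items recoded 0-0-1-1) is
#' available via `scoring = "binary"`.
#'
#' @param item_scores Numeric matrix or data frame, samples x 28 items,
#'   each entry in \{0, 1, 2, 3\}.
#' @param scoring `"likert"` (default; item values summed as-is) or
#'   `"binary"` (items recoded to 0, 0, 1, 1 before summing).
#' @return Numeric vector `log(1 + raw sum)`.
#' @examples
#' transform_ghq(matrix(0, 1, 28))        # 0
#' transform_ghq(matrix(3, 1, 28))        # log(85)
#' @export
transform_ghq <- function(item_scores, scoring = c("likert", "binary")) {
  scoring <- match.arg(scoring)
  x <- as.matrix(item_scores)
  if (ncol(x) != 28) stop("GHQ requires 28 item columns", call. = FALSE)
  bad <- !is.na(x) & !(x %in% 0:3)
  if (any(bad)) stop("GHQ items must be in {0, 1, 2, 3}", call. = FALSE)
  x[is.na(x)] <- 0
  if (scoring == "binary") x <- (x >= 2) + 0
  log1p(rowSums(x))
}

#' Bin a raw PHQ sum into the four-point score
#'
#' Maps the raw sum onto \{0, 1, 2, 3\}: 0 -> 0, 1-2 -> 1, 3-5 -> 2,
#' >= 6 -> 3 — the recode used to normalise a strongly skewed
#' short-form depressive-symptom distribution.
#'
#' @param raw_sum Non-negative integer vector of raw PHQ sums.
#' @return Integer vector of categories in \{0, 1, 2, 3\}.
#' @examples
#' bin_phq(c(0, 1, 2, 3, 5, 6, 12))
#' @export
bin_phq <- function(raw_sum) {
  if (any(!is.na(raw_sum) & raw_sum < 0)) {
    stop("`raw_sum` must be non-negative", call. = FALSE)
  }
  as.integer(cut(raw_sum, breaks = c(-0.5, 0.5, 2.5, 5.5, Inf),
                 labels = FALSE)) - 1L
}

#' Label proxy cases from first-degree relatives
#'
#' Implements mapping-by-proxy: individuals who are not themselves cases
#' but have at least one first-degree relative who is a case are
#' labelled `proxy_case` and pooled with the cases in downstream
#' case-control analyses; everyone else is a control. A sample that is a
#' case is never demoted to proxy.
#'
#' @param case_status Data frame with columns `iid` and `case` (logical
#'   or 0/1).
#' @param relatives Data frame with columns `iid1`, `iid2`, one row per
#'   first-degree pair (undirected); may be empty.
#' @return Tibble with `iid`, `status` in
#'   \{"case","proxy_case","control"\} and `source` in
#'   \{"self_report","first_degree_relative",NA\}.
#' @examples
#' st <- tibble::tibble(iid = c("a", "b", "c"), case = c(TRUE, FALSE, FALSE))
#' rel <- tibble::tibble(iid1 = "a", iid2 = "b")
#' map_proxy_cases(st, rel)
#' @export
map_proxy_cases <- function(case_status, relatives = NULL) {
  stopifnot(all(c("iid", "case") %in% names(case_status)))
  case <- as.logical(case_status$case)
  iid <- as.character(case_status$iid)
  proxy <- rep(FALSE, length(iid))
  if (!is.null(relatives) && nrow(relatives) > 0) {
    r1 <- as.character(relatives$iid1)
    r2 <- as.character(relatives$iid2)
    if (any(r1 == r2)) stop("a sample cannot be its own relative", call. = FALSE)
    unknown <- setdiff(c(r1, r2), iid)
    if (length(unknown) > 0) {
      stop("relative pair references unknown sample(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    case_set <- iid[case]
    has_case_rel <- iid %in% c(r2[r1 %in% case_set], r1[r2 %in% case_set])
    proxy <- !case & has_case_rel
  }
  tibble::tibble(
    iid = iid,
    status = dplyr::case_when(case ~ "case", proxy ~ "proxy_case",
                              TRUE ~ "control"),
    source = dplyr::case_when(case ~ "self_report",
                              proxy ~ "first_degree_relative",
                              TRUE ~ NA_character_)
  )
}
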