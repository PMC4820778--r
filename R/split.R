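#' Split clinically normal specimens by preterminal tortuosity
#'
#' Clinically normal placentas are divided at a threshold on the specimen
#' mean tortuosity of directly preterminal (bT1) branches: above the
#' threshold they are `HT-normal` (high tortuosity), below `LT-normal`.
#' Values exactly at the threshold are labelled `LT-normal` with a
#' warning (the high group is defined by strictly exceeding the cutoff).
#' IUGR specimens keep their label.  Specimens without bT1 branches
#' (missing mean) cannot be subgrouped and get `NA` with a warning.
#'
#' @param aggregates data.frame from [aggregate_specimens()] (needs
#'   columns `specimen_id`, `group`, `mt_bT1`).
#' @param threshold tortuosity cutoff, > 1; default 1.2.
#' @param normal_label the label of the clinically normal group in
#'   `aggregates$group`.
#' @return Character vector of subgroup labels aligned with
#'   `aggregates` rows: `"IUGR"`, `"HT-normal"`, `"LT-normal"` or `NA`.
#' @export
split_ht_lt <- function(aggregates, threshold = 1.2, normal_label = "normal") {
  stopifnot(threshold > 1,
            all(c("specimen_id", "group", "mt_bT1") %in% names(aggregates)))
  lab <- as.character(aggregates$group)
  norm <- lab == normal_label
  mt1 <- aggregates$mt_bT1
  miss <- norm & is.na(mt1)
  if (any(miss)) {
    warning(sum(miss), " normal specimen(s) without bT1 branches excluded ",
            "from subgrouping: ",
            paste(aggregates$specimen_id[miss], collapse = ", "))
    lab[miss] <- NA_character_
  }
  at <- norm & !is.na(mt1) & mt1 == threshold
  if (any(at))
    warning("specimen(s) exactly at the threshold labelled LT-normal: ",
            paste(aggregates$specimen_id[at], collapse = ", "))
  hi <- norm & !is.na(mt1) & mt1 > threshold
  lo <- norm & !is.na(mt1) & mt1 <= threshold
  lab[hi] <- "HT-normal"
  lab[lo] <- "LT-normal"
  lab
}
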