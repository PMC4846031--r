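#' Per-source disease and pair count table
#'
#' Container for the counts a 2x2 comorbidity analysis needs from one EMR
#' source: the roster total `N` (all patients in the system, including those
#' with no mapped disease), per-disease patient counts `n_i`, and
#' per-unordered-pair co-occurrence counts `d_ij` keyed lexicographically.
#'
#' @param total_patients Roster total `N`.
#' @param disease_counts Named nonnegative integer vector, one entry per
#'   disease.
#' @param pair_counts data.frame with columns `disease1`, `disease2`,
#'   `count`; pairs are canonicalized and aggregated.  Pairs absent from the
#'   table are implicitly zero.
#' @param source_label Text label for the source system.
#' @return An object of class `pair_count_table`.
#' @export
pair_count_table <- function(total_patients, disease_counts,
                             pair_counts = NULL, source_label = "emr") {
  total_patients <- as.integer(total_patients)
  stopifnot(total_patients >= 0, !is.null(names(disease_counts)))
  disease_counts <- setNames(as.integer(disease_counts), names(disease_counts))
  if (any(disease_counts < 0)) stop("negative disease count")
  bad <- names(disease_counts)[disease_counts > total_patients]
  if (length(bad))
    stop("disease count exceeds roster total for: ", paste(bad, collapse = ", "))
  if (is.null(pair_counts)) {
    pair_counts <- data.frame(disease1 = character(), disease2 = character(),
                              count = integer(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("disease1", "disease2", "count") %in% names(pair_counts)))
    cp <- canonical_pair(pair_counts$disease1, pair_counts$disease2)
    pc <- data.table::data.table(cp, count = as.integer(pair_counts$count))
    pc <- pc[, list(count = sum(count)), by = c("disease1", "disease2")]
    data.table::setorder(pc, disease1, disease2)
    pair_counts <- as.data.frame(pc)
    unknown <- setdiff(unique(c(pair_counts$disease1, pair_counts$disease2)),
                       names(disease_counts))
    if (length(unknown))
      stop("pair counts reference unknown diseases: ",
           paste(unknown, collapse = ", "))
    cap <- pmin(disease_counts[pair_counts$disease1],
                disease_counts[pair_counts$disease2])
    over <- pair_counts$count > cap
    if (any(over))
      stop("pair count exceeds a marginal count for: ",
           paste(paste(pair_counts$disease1[over], pair_counts$disease2[over],
                       sep = " / "), collapse = ", "))
  }
  structure(list(total_patients = total_patients,
                 disease_counts = disease_counts,
                 pair_counts = pair_counts,
                 source_label = source_label),
            class = "pair_count_table")
}

#' @export
print.pair_count_table <- function(x, ...) {
  cat(sprintf("<pair_count_table '%s': N = %d, %d diseases, %d nonzero pairs>\n",
              x$source_label, x$total_patients, length(x$disease_counts),
              nrow(x$pair_counts)))
  invisible(x)
}

# look up d_ij (0 when the pair is not recorded)
pair_count <- function(table, d1, d2) {
  ids <- pair_id(table$pair_counts$disease1, table$pair_counts$disease2)
  hit <- match(pair_id(d1, d2), ids)
  out <- table$pair_counts$count[hit]
  out[is.na(out)] <- 0L
  out
}

#' Read encounter-level EMR records
#'
#' Reads a comma-separated encounter file with header columns `patient_id`,
#' `icd9`, `age_at_visit`, `visit_year`.  Records before `year_min` are
#' dropped (EMR systems typically have a comprehensive-rollout year before
#' which coding is unreliable) and ages above `age_cap` are censored to the
#' cap, matching the privacy censoring applied by record systems.  Rows with
#' unparseable age or year are dropped with a warning that lists their line
#' numbers.
#'
#' @param path CSV file path.
#' @param year_min Minimum visit year retained (default 2008).
#' @param age_cap Age ceiling in years (default 90).
#' @return data.frame with columns `patient_id`, `icd9`, `age_at_visit`,
#'   `visit_year`.
#' @export
read_encounters <- function(path, year_min = 2008, age_cap = 90) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  req <- c("patient_id", "icd9", "age_at_visit", "visit_year")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols))
    stop("encounter file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  age <- suppressWarnings(as.integer(raw$age_at_visit))
  year <- suppressWarnings(as.integer(raw$visit_year))
  bad <- which(is.na(age) | is.na(year) | raw$icd9 == "" | age < 0)
  if (length(bad))
    warning(sprintf("dropped %d malformed encounter row(s) at line(s): %s",
                    length(bad),
                    paste(utils::head(bad + 1L, 20L), collapse = ", ")))
  keep <- setdiff(seq_len(nrow(raw)), bad)
  out <- data.frame(patient_id = raw$patient_id[keep],
                    icd9 = raw$icd9[keep],
                    age_at_visit = pmin(age[keep], as.integer(age_cap)),
                    visit_year = year[keep],
                    stringsAsFactors = FALSE)
  out[out$visit_year >= year_min, , drop = FALSE]
}

#' Read an ICD9-to-disease catalog
#'
#' Many ICD9 codes map to one disease name; every code must map to exactly
#' one disease.
#'
#' @param path CSV with header columns `icd9`, `disease`.
#' @return Named character vector: `icd9 -> disease`.
#' @export
read_catalog <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("icd9", "disease") %in% names(raw)))
    stop("catalog file must have columns 'icd9' and 'disease'")
  dup <- raw$icd9[duplicated(raw$icd9)]
  if (length(dup))
    stop("ICD9 code(s) mapped to more than one disease: ",
         paste(unique(dup), collapse = ", "))
  setNames(raw$disease, raw$icd9)
}

#' Reduce encounters to earliest disease onset per patient
#'
#' Maps each encounter's ICD9 code to a disease name through the catalog and
#' keeps, for every (patient, disease), the minimum age across all of that
#' patient's encounters for any code mapping to the disease.  Codes not in
#' the catalog are skipped (a deliberately restricted disease catalog is the
#' normal case); their distinct count is attached as attribute
#' `n_unmapped_codes`.
#'
#' @param encounters data.frame from [read_encounters()].
#' @param catalog Named character vector from [read_catalog()].
#' @return data.frame `patient_id`, `disease`, `onset_age`, one row per
#'   (patient, disease).
#' @export
earliest_onset <- function(encounters, catalog) {
  disease <- unname(catalog[encounters$icd9])
  mapped <- !is.na(disease)
  n_unmapped <- length(unique(encounters$icd9[!mapped]))
  dt <- data.table::data.table(patient_id = encounters$patient_id[mapped],
                               disease = disease[mapped],
                               age = encounters$age_at_visit[mapped])
  if (nrow(dt) == 0L) {
    out <- data.frame(patient_id = character(), disease = character(),
                      onset_age = integer(), stringsAsFactors = FALSE)
  } else {
    dt <- dt[, list(onset_age = min(age)), by = c("patient_id", "disease")]
    data.table::setorder(dt, patient_id, disease)
    out <- as.data.frame(dt)
  }
  attr(out, "n_unmapped_codes") <- n_unmapped
  out
}

#' Count diseases, disease pairs, and onset-age histograms
#'
#' From the earliest-onset table, computes per-disease distinct-patient
#' counts, per-pair co-occurrence counts, and the 91-bin (ages 0..90)
#' earliest-onset histogram for each disease.  `roster_total` is the full
#' patient count of the source system, including patients with no mapped
#' disease — it is what fills the "neither disease" cell of the 2x2 table
#' downstream, so it must be supplied rather than inferred.
#'
#' @param onsets data.frame from [earliest_onset()].
#' @param roster_total Total patients in the source system.
#' @param source_label Source system label.
#' @return list with `counts` (a [pair_count_table()]) and `histograms`
#'   (integer matrix, diseases x 91 with columns named "0".."90"; row sums
#'   equal the disease counts).
#' @export
count_diseases_and_pairs <- function(onsets, roster_total,
                                     source_label = "emr") {
  n_obs <- length(unique(onsets$patient_id))
  if (roster_total < n_obs)
    stop(sprintf("roster_total (%d) is smaller than the %d distinct patients observed",
                 roster_total, n_obs))
  if (nrow(onsets) == 0L) {
    return(list(counts = pair_count_table(roster_total,
                                          setNames(integer(), character()),
                                          source_label = source_label),
                histograms = matrix(0L, 0, 91,
                                    dimnames = list(NULL, as.character(0:90)))))
  }
  dt <- data.table::as.data.table(onsets)
  n_i <- dt[, list(n = data.table::uniqueN(patient_id)), by = "disease"]
  disease_counts <- setNames(n_i$n, n_i$disease)
  # pairs: self-join patient disease sets
  pairs <- merge(dt[, c("patient_id", "disease")],
                 dt[, c("patient_id", "disease")],
                 by = "patient_id", allow.cartesian = TRUE)
  pairs <- pairs[pairs$disease.x < pairs$disease.y, ]
  pair_counts <- pairs[, list(count = data.table::uniqueN(patient_id)),
                       by = c("disease.x", "disease.y")]
  data.table::setnames(pair_counts, c("disease.x", "disease.y"),
                       c("disease1", "disease2"))
  diseases <- sort(names(disease_counts))
  hist <- matrix(0L, length(diseases), 91,
                 dimnames = list(diseases, as.character(0:90)))
  hc <- dt[, list(n = .N), by = c("disease", "onset_age")]
  hist[cbind(hc$disease, as.character(hc$onset_age))] <- hc$n
  list(counts = pair_count_table(roster_total, disease_counts,
                                 as.data.frame(pair_counts), source_label),
       histograms = hist)
}

#' Remove diseases with too few patients
#'
#' Diseases observed in fewer than `min_patients` patients are judged too
#' rare to contribute meaningful incidence frequencies and are removed along
#' with all their pairs.  The comparison is strict (`n_i < min_patients`
#' removes), so a disease with exactly `min_patients` patients is retained.
#' The roster total `N` is unchanged.
#'
#' @param table A [pair_count_table()].
#' @param min_patients Threshold (default 50).
#' @return Filtered `pair_count_table`.
#' @export
filter_rare <- function(table, min_patients = 50) {
  stopifnot(inherits(table, "pair_count_table"), min_patients >= 0)
  keep <- names(table$disease_counts)[table$disease_counts >= min_patients]
  pc <- table$pair_counts
  pc <- pc[pc$disease1 %in% keep & pc$disease2 %in% keep, , drop = FALSE]
  pair_count_table(table$total_patients, table$disease_counts[keep],
                   pc, table$source_label)
}

#' Read aggregate per-disease and per-pair count tables
#'
#' For sources where patient-level records are unavailable and only published
#' aggregate counts exist.  The roster total may require a downward
#' adjustment when the published total includes people who are not patients
#' (for example healthy hospital employees enrolled in the system); the
#' adjustment is applied to `N` only, the counts are loaded verbatim.
#'
#' @param disease_count_path CSV with columns `disease`, `count`.
#' @param pair_count_path CSV with columns `disease1`, `disease2`, `count`.
#' @param roster_total Published total patient count.
#' @param total_adjustment Nonnegative count subtracted from `roster_total`.
#' @param source_label Source system label.
#' @return A [pair_count_table()] with `N = roster_total - total_adjustment`.
#' @export
read_aggregate_counts <- function(disease_count_path, pair_count_path,
                                  roster_total, total_adjustment = 0,
                                  source_label = "aggregate") {
  stopifnot(total_adjustment >= 0)
  if (total_adjustment > roster_total)
    stop("total_adjustment exceeds roster_total")
  dc <- utils::read.csv(disease_count_path, stringsAsFactors = FALSE)
  if (!all(c("disease", "count") %in% names(dc)))
    stop("disease count file must have columns 'disease' and 'count'")
  pc <- utils::read.csv(pair_count_path, stringsAsFactors = FALSE)
  if (!all(c("disease1", "disease2", "count") %in% names(pc)))
    stop("pair count file must have columns 'disease1', 'disease2', 'count'")
  N <- roster_total - total_adjustment
  if (any(dc$count > N))
    stop("adjusted roster total is smaller than the count for: ",
         paste(dc$disease[dc$count > N], collapse = ", "))
  pair_count_table(N, setNames(dc$count, dc$disease), pc, source_label)
}

#' Disease frequency as a percent of the roster
#'
#' @param count Patient count (0 <= count <= total).
#' @param total Roster total (> 0).
#' @return `100 * count / total`, rounded half-even to two decimals, the
#'   convention used in published EMR frequency tables.
#' @export
frequency_percent <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(count < 0 | count > total)) stop("count must be in [0, total]")
  round(100 * count / total, 2)
}
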