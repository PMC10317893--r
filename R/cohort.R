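# Cohort container, schema validation and CSV input/output.
#
# A cohort is a data.frame (class "tg_cohort") with one row per patient and
# the canonical columns below. Enum columns are stored as factors with fixed
# level sets; `center` is a passive label and is never offered to the tree
# as a predictor.

#' Canonical cohort schema
#'
#' Column names, enum vocabularies and predictor ordering used throughout
#' the package.
#'
#' @format A list with components `columns` (canonical column names),
#'   `levels` (enum vocabularies), and `predictors` (the nine candidate
#'   predictors in their canonical reporting order).
#' @export
tg_schema <- list(
  columns = c("age", "sex", "histology", "t_stage", "n_stage", "ata_risk",
              "tsh", "tg", "raiu", "ptwbs", "center"),
  levels = list(
    sex       = c("M", "F"),
    histology = c("PTC", "PTC-FV", "FTC", "HCTC"),
    ata_risk  = c("low", "intermediate", "high"),
    ptwbs     = c("negative", "remnant", "positive")
  ),
  # canonical predictor order, used for deterministic tie-breaking
  predictors = c("tg", "n_stage", "sex", "t_stage", "histology",
                 "ata_risk", "tsh", "age", "raiu")
)

# accepted case-insensitive header aliases -> canonical names
.tg_aliases <- c(
  age = "age", sex = "sex", gender = "sex",
  histology = "histology", histotype = "histology",
  t_stage = "t_stage", t = "t_stage", tstage = "t_stage",
  n_stage = "n_stage", n = "n_stage", nstage = "n_stage",
  ata_risk = "ata_risk", ata = "ata_risk", atarisk = "ata_risk",
  tsh = "tsh", tg = "tg", thyroglobulin = "tg",
  raiu = "raiu", uptake = "raiu",
  ptwbs = "ptwbs", pt_wbs = "ptwbs", wbs = "ptwbs",
  center = "center", centre = "center", site = "center"
)

.mandatory_cols <- setdiff(tg_schema$columns, "center")

#' Construct a validated cohort
#'
#' Checks every record against the schema invariants (age >= 18, tsh > 0,
#' tg >= 0, raiu in [0, 100], enum membership) and coerces enum columns to
#' factors with the canonical level sets. Rows violating any invariant are
#' rejected; the rejections are recorded in the parse report attached as
#' attribute `"report"`.
#'
#' @param df A data.frame with (at least) the mandatory schema columns.
#' @param provenance Free-text source tag stored on the cohort.
#' @param seed Optional integer recorded for provenance (not consumed).
#' @return A `tg_cohort` data.frame with attributes `provenance`, `seed` and
#'   `report` (a list with `rows_read`, `rows_kept`, `rejects`).
#' @export
as_tg_cohort <- function(df, provenance = "unspecified", seed = NULL) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.mandatory_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"center" %in% names(df)) df$center <- NA_character_
  df <- df[tg_schema$columns]
  n <- nrow(df)

  num_or_na <- function(v) suppressWarnings(as.numeric(v))
  age  <- num_or_na(df$age)
  tsh  <- num_or_na(df$tsh)
  tg   <- num_or_na(df$tg)
  raiu <- num_or_na(df$raiu)
  tst  <- num_or_na(df$t_stage)
  nst  <- num_or_na(df$n_stage)

  reason <- character(n)
  flag <- function(bad, why) {
    bad <- which(bad & reason == "")
    reason[bad] <<- why
  }
  flag(is.na(age) | age < 18 | age != round(age), "invalid age (integer >= 18 required)")
  flag(!(as.character(df$sex) %in% tg_schema$levels$sex), "unknown sex label")
  flag(!(as.character(df$histology) %in% tg_schema$levels$histology), "unknown histology label")
  flag(is.na(tst) | !(tst %in% 1:4), "invalid T stage (1-4)")
  flag(is.na(nst) | !(nst %in% 0:1), "invalid N stage (0/1)")
  flag(!(as.character(df$ata_risk) %in% tg_schema$levels$ata_risk), "unknown ATA risk label")
  flag(is.na(tsh) | tsh <= 0, "invalid TSH (positive required)")
  flag(is.na(tg) | tg < 0, "invalid Tg (non-negative required)")
  flag(is.na(raiu) | raiu < 0 | raiu > 100, "invalid RAIU (0-100 required)")
  flag(!(as.character(df$ptwbs) %in% tg_schema$levels$ptwbs), "unknown endpoint label")

  keep <- reason == ""
  rejects <- if (all(keep)) {
    data.frame(row = integer(0), reason = character(0))
  } else {
    data.frame(row = which(!keep), reason = reason[!keep])
  }

  out <- data.frame(
    age       = as.integer(age[keep]),
    sex       = factor(as.character(df$sex)[keep], levels = tg_schema$levels$sex),
    histology = factor(as.character(df$histology)[keep], levels = tg_schema$levels$histology),
    t_stage   = as.integer(tst[keep]),
    n_stage   = as.integer(nst[keep]),
    ata_risk  = factor(as.character(df$ata_risk)[keep],
                       levels = tg_schema$levels$ata_risk, ordered = TRUE),
    tsh       = tsh[keep],
    tg        = tg[keep],
    raiu      = raiu[keep],
    ptwbs     = factor(as.character(df$ptwbs)[keep], levels = tg_schema$levels$ptwbs),
    center    = { cc <- as.character(df$center)[keep]; cc[!is.na(cc) & cc == ""] <- NA; cc },
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
            class = c("tg_cohort", "data.frame"),
            provenance = provenance,
            seed = seed,
            report = list(rows_read = n, rows_kept = sum(keep), rejects = rejects))
}

#' Read a patient cohort from CSV
#'
#' Comma-separated, UTF-8, "." decimal, mandatory header. Header names are
#' matched case-insensitively and common aliases (e.g. `gender` for `sex`,
#' `N` for `n_stage`) are accepted. Invalid rows are rejected with a
#' per-row reason; the parse report is attached as attribute `"report"`.
#'
#' @param path Path to a CSV file.
#' @param provenance Source tag stored on the returned cohort (defaults to
#'   the file path).
#' @return A validated [as_tg_cohort()] cohort, row order preserved.
#' @export
read_cohort_csv <- function(path, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  nm <- tolower(trimws(names(raw)))
  canon <- unname(.tg_aliases[nm])
  dup <- duplicated(canon, incomparables = NA)
  if (any(dup)) stop("duplicate column after alias resolution: ",
                     paste(unique(canon[dup]), collapse = ", "))
  names(raw)[!is.na(canon)] <- canon[!is.na(canon)]
  missing_cols <- setdiff(.mandatory_cols, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  as_tg_cohort(raw, provenance = provenance)
}

#' Write a cohort to CSV
#'
#' Deterministic canonical column order; numeric values are written at full
#' double precision so that [read_cohort_csv()] round-trips the cohort
#' field-by-field.
#'
#' @param cohort A `tg_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "tg_cohort"))
  df <- as.data.frame(cohort)[tg_schema$columns]
  for (col in c("sex", "histology", "ata_risk", "ptwbs")) {
    df[[col]] <- as.character(df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Binarize the scintigraphy endpoint
#'
#' The modeled endpoint is the presence of metastatic uptake on the
#' post-treatment whole-body scan: `positive` (pathological uptake outside
#' the thyroid bed) maps to 1; `negative` and `remnant` (thyroid-bed uptake
#' only, not disease for this endpoint) map to 0.
#'
#' @param ptwbs Character or factor vector of scan labels.
#' @return Integer vector of 0/1.
#' @export
binarize_endpoint <- function(ptwbs) {
  lab <- as.character(ptwbs)
  bad <- !(lab %in% tg_schema$levels$ptwbs)
  if (any(bad)) stop("unknown endpoint label: ", paste(unique(lab[bad]), collapse = ", "))
  as.integer(lab == "positive")
}

#' @export
print.tg_cohort <- function(x, ...) {
  rep <- attr(x, "report")
  cat(sprintf("Patient cohort: %d records (source: %s)\n",
              nrow(x), attr(x, "provenance")))
  if (!is.null(rep) && nrow(rep$rejects) > 0L) {
    cat(sprintf("  %d of %d input rows rejected during validation\n",
                nrow(rep$rejects), rep$rows_read))
  }
  y <- binarize_endpoint(x$ptwbs)
  cat(sprintf("  positive PT-WBS: %d (%.1f%%)\n", sum(y), 100 * mean(y)))
  invisible(x)
}
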