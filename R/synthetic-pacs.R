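# Synthetic DICOM cohort generator and in-process query/retrieve provider.
# Stands in for a production PACS: generates a reproducible patient ->
# study -> series -> image tree as DICOM Part 10 files plus paired
# radiology-report stubs, and serves it through the provider contract
# consumed by the query/retrieve client.

.UID_ROOT <- "1.3.6.1.4.1.99999.1"

#' Specification of a synthetic PACS cohort
#'
#' Defaults are calibrated so that a 1000-patient cohort reproduces the
#' per-patient shape of a university-hospital PACS sample: 98.8% of
#' patients with imaging, right-skewed counts with median (quartiles) of
#' about 3 (1-8) studies, 10 (3-29) series and 103 images per patient,
#' a CT/CR/MR/US modality mix, and per-image payloads whose full-scale
#' median is 566.4 KiB (shrunk by `size_scale` for fast tests).
#'
#' Counts are drawn from rounded log-normal distributions truncated at 1.
#' Images per series additionally carry a patient-level log-normal random
#' effect (`patient_sdlog`), reflecting that a patient's series tend to be
#' jointly small (e.g. radiographs) or jointly large (e.g. CT volumes).
#'
#' @param n_patients Number of patients in the cohort.
#' @param p_has_imaging Probability that a patient has any imaging.
#' @param studies_dist,series_per_study_dist,images_per_series_dist Lists
#'   with `meanlog` and `sdlog` (and for images `patient_sdlog`) of the
#'   rounded, >= 1 truncated log-normal count distributions.
#' @param modality_weights Named probability vector over modality codes.
#' @param image_payload_bytes_dist List with `meanlog` and `sdlog` of the
#'   log-normal per-image payload size (bytes, at `size_scale = 1`).
#' @param size_scale Multiplier on payload sizes; the default keeps test
#'   images near 64x64 pixels. Set to 1 for realistic image sizes.
#' @param date_range Length-2 `Date` (or coercible) interval for StudyDate.
#' @param inconsistency_rate Probability that an image file carries a
#'   series identifier that disagrees with the PACS index, emulating
#'   DICOM files imported from external hospitals.
#' @param report_fraction Fraction of studies with a paired radiology
#'   report document (chosen deterministically, not randomly).
#' @param seed Integer seed; identical spec and seed give a byte-identical
#'   generated tree.
#' @return A validated object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 1000L,
                        p_has_imaging = 0.988,
                        studies_dist = list(meanlog = log(3), sdlog = 1.54),
                        series_per_study_dist = list(meanlog = log(2.4), sdlog = 0.80),
                        images_per_series_dist = list(meanlog = log(7.05), sdlog = 0.90,
                                                      patient_sdlog = 0.90),
                        modality_weights = c(CT = 0.40, CR = 0.30, MR = 0.20, US = 0.10),
                        image_payload_bytes_dist = list(meanlog = log(566.4 * 1024),
                                                        sdlog = 1.0),
                        size_scale = 1 / 128,
                        date_range = as.Date(c("2015-01-01", "2019-12-31")),
                        inconsistency_rate = 0.003,
                        report_fraction = 0.8,
                        seed = 20200420L) {
  spec <- structure(list(
    n_patients = n_patients, p_has_imaging = p_has_imaging,
    studies_dist = studies_dist, series_per_study_dist = series_per_study_dist,
    images_per_series_dist = images_per_series_dist,
    modality_weights = modality_weights,
    image_payload_bytes_dist = image_payload_bytes_dist,
    size_scale = size_scale, date_range = as.Date(date_range),
    inconsistency_rate = inconsistency_rate,
    report_fraction = report_fraction, seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Validate a cohort specification
#'
#' @param spec A `cohort_spec`.
#' @return `spec`, invisibly; errors name the offending field.
#' @export
validate_cohort_spec <- function(spec) {
  fail <- function(field, why) stop("invalid cohort spec: field '", field, "' ", why,
                                    call. = FALSE)
  n <- spec$n_patients
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    fail("n_patients", "must be a single non-negative integer")
  for (f in c("p_has_imaging", "inconsistency_rate", "report_fraction")) {
    p <- spec[[f]]
    if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
      fail(f, "must be a probability in [0, 1]")
  }
  for (f in c("studies_dist", "series_per_study_dist", "images_per_series_dist",
              "image_payload_bytes_dist")) {
    d <- spec[[f]]
    if (!is.list(d) || is.null(d$meanlog) || is.null(d$sdlog))
      fail(f, "must be a list with meanlog and sdlog")
    if (d$sdlog < 0) fail(f, "sdlog must be >= 0")
  }
  w <- spec$modality_weights
  if (is.null(names(w)) || any(is.na(w)) || any(w < 0) ||
      abs(sum(w) - 1) > 1e-8)
    fail("modality_weights", "must be named, non-negative and sum to 1")
  if (length(spec$date_range) != 2L || any(is.na(spec$date_range)) ||
      spec$date_range[1] > spec$date_range[2])
    fail("date_range", "must be an ordered pair of dates")
  if (spec$size_scale <= 0) fail("size_scale", "must be positive")
  if (length(spec$seed) != 1L || is.na(spec$seed))
    fail("seed", "must be a single integer")
  invisible(spec)
}

#' Read a cohort specification from a YAML file
#'
#' Fields missing from the file keep their `cohort_spec()` defaults.
#'
#' @param path YAML file path.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$modality_weights)) cfg$modality_weights <- unlist(cfg$modality_weights)
  do.call(cohort_spec, cfg)
}

# rounded lognormal truncated at 1
.rdisc <- function(n, meanlog, sdlog) {
  pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.BODY_PARTS <- c("THORAX", "ABDOMEN", "HEAD", "SPINE", "PELVIS", "EXTREMITY")
.SERIES_PROTOCOLS <- c("axial", "sagittal", "coronal", "scout", "contrast", "native")
.MANUFACTURERS <- c("Siemens", "GE Healthcare", "Philips", "Canon Medical")
.MODELS <- c("Definition AS", "Revolution", "Ingenia", "Aquilion ONE")

#' Sample the index of a synthetic cohort
#'
#' Draws the full patient/study/series/image index (identifiers,
#' modalities, dates, descriptions, payload sizes, inconsistency and
#' report flags) without writing any files. [gen_cohort()] materializes
#' this index to disk; sampling alone is sufficient for calibration
#' checks and large-cohort statistics.
#'
#' The caller's RNG state is left untouched; all draws come from a
#' stream seeded with `spec$seed`, so the same spec always yields the
#' same index.
#'
#' @param spec A `cohort_spec`.
#' @return An object of class `pacs_cohort`: list of data.tables
#'   `patients`, `studies`, `series`, `images` plus the `spec`.
#' @export
sample_cohort <- function(spec) {
  validate_cohort_spec(spec)
  .with_seed(spec$seed, {
    n <- as.integer(spec$n_patients)
    empty <- function() {
      structure(list(
        spec = spec,
        patients = data.table(patient_id = character(), has_imaging = logical(),
                              patient_name = character(), birth_date = character(),
                              sex = character()),
        studies = data.table(patient_id = character(), study_uid = character(),
                             accession_number = character(), study_date = character(),
                             study_time = character(), study_description = character(),
                             modality_primary = character(), has_report = logical()),
        series = data.table(patient_id = character(), study_uid = character(),
                            series_uid = character(), series_number = integer(),
                            modality = character(), series_description = character(),
                            body_part = character()),
        images = data.table(patient_id = character(), study_uid = character(),
                            series_uid = character(), sop_uid = character(),
                            instance_number = integer(), modality = character(),
                            payload_bytes = numeric(), side_px = integer(),
                            inconsistent = logical())
      ), class = "pacs_cohort")
    }
    if (n == 0L) return(empty())

    pid <- sprintf("PID%06d", seq_len(n))
    has_imaging <- stats::runif(n) < spec$p_has_imaging
    surnames <- c("MUELLER", "SCHMIDT", "WEBER", "FISCHER", "WAGNER", "BECKER",
                  "HOFFMANN", "SCHULZ", "KOCH", "RICHTER")
    given <- c("ANNA", "PETER", "MARIA", "HANS", "JULIA", "KARL", "EVA", "MAX")
    patient_name <- paste0(sample(surnames, n, TRUE), "^", sample(given, n, TRUE))
    birth_date <- format(as.Date("1930-01-01") +
                           sample.int(25000L, n, TRUE), "%Y%m%d")
    sex <- sample(c("M", "F"), n, TRUE)
    patients <- data.table(patient_id = pid, has_imaging = has_imaging,
                           patient_name = patient_name, birth_date = birth_date,
                           sex = sex)

    imaged <- which(has_imaging)
    if (length(imaged) == 0L) return(empty())
    sd_ <- spec$studies_dist; kd <- spec$series_per_study_dist
    md <- spec$images_per_series_dist
    n_studies <- .rdisc(length(imaged), sd_$meanlog, sd_$sdlog)

    ip_of_study <- rep(imaged, n_studies)            # patient row per study
    ns_total <- length(ip_of_study)
    study_ord <- sequence(n_studies)                 # ordinal within patient
    uidp <- paste0(.UID_ROOT, ".", spec$seed)
    study_uid <- paste0(uidp, ".", ip_of_study, ".", study_ord)
    accession <- sprintf("A%08d", seq_len(ns_total))
    span <- as.integer(spec$date_range[2] - spec$date_range[1])
    study_date <- format(spec$date_range[1] + sample.int(span + 1L, ns_total, TRUE) - 1L,
                         "%Y%m%d")
    study_time <- sprintf("%02d%02d%02d", sample.int(24L, ns_total, TRUE) - 1L,
                          sample.int(60L, ns_total, TRUE) - 1L,
                          sample.int(60L, ns_total, TRUE) - 1L)
    mods <- names(spec$modality_weights)
    modality_primary <- sample(mods, ns_total, TRUE, prob = spec$modality_weights)
    body_part_study <- sample(.BODY_PARTS, ns_total, TRUE)
    study_description <- paste(modality_primary, body_part_study)
    frac <- spec$report_fraction
    has_report <- floor(seq_len(ns_total) * frac) > floor((seq_len(ns_total) - 1L) * frac)
    studies <- data.table(patient_id = pid[ip_of_study], study_uid = study_uid,
                          accession_number = accession, study_date = study_date,
                          study_time = study_time,
                          study_description = study_description,
                          modality_primary = modality_primary,
                          has_report = has_report)

    n_series <- .rdisc(ns_total, kd$meanlog, kd$sdlog)
    st_of_series <- rep(seq_len(ns_total), n_series)
    nk_total <- length(st_of_series)
    series_number <- sequence(n_series)
    series_uid <- paste0(study_uid[st_of_series], ".", series_number)
    same <- stats::runif(nk_total) < 0.85           # most series share the study modality
    modality <- ifelse(same, modality_primary[st_of_series],
                       sample(mods, nk_total, TRUE, prob = spec$modality_weights))
    series_description <- paste0(sample(.SERIES_PROTOCOLS, nk_total, TRUE), " ",
                                 series_number)
    series <- data.table(patient_id = pid[ip_of_study][st_of_series],
                         study_uid = study_uid[st_of_series],
                         series_uid = series_uid, series_number = series_number,
                         modality = modality,
                         series_description = series_description,
                         body_part = body_part_study[st_of_series])

    u_pat <- stats::rnorm(n, 0, md$patient_sdlog %||% 0)
    ip_of_series <- ip_of_study[st_of_series]
    n_images <- .rdisc(nk_total, md$meanlog + u_pat[ip_of_series], md$sdlog)
    se_of_image <- rep(seq_len(nk_total), n_images)
    ni_total <- length(se_of_image)
    instance_number <- sequence(n_images)
    sop_uid <- paste0(series_uid[se_of_image], ".", instance_number)
    pb <- spec$image_payload_bytes_dist
    payload <- stats::rlnorm(ni_total, pb$meanlog + log(spec$size_scale), pb$sdlog)
    side <- pmin(2048L, pmax(8L, as.integer(round(sqrt(payload)))))
    inconsistent <- stats::runif(ni_total) < spec$inconsistency_rate
    images <- data.table(patient_id = pid[ip_of_series][se_of_image],
                         study_uid = study_uid[st_of_series][se_of_image],
                         series_uid = series_uid[se_of_image], sop_uid = sop_uid,
                         instance_number = instance_number,
                         modality = modality[se_of_image],
                         payload_bytes = as.numeric(side)^2, side_px = side,
                         inconsistent = inconsistent)

    structure(list(spec = spec, patients = patients, studies = studies,
                   series = series, images = images),
              class = "pacs_cohort")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-patient study/series/image counts of a cohort
#'
#' @param cohort A `pacs_cohort` (from [sample_cohort()] or a tree's
#'   `$cohort`).
#' @return data.table with one row per patient: `patient_id`, `detected`
#'   (has any imaging), `n_studies`, `n_series`, `n_images`.
#' @export
per_patient_counts <- function(cohort) {
  stopifnot(inherits(cohort, "pacs_cohort"))
  pats <- cohort$patients[, c("patient_id", "has_imaging")]
  cs <- cohort$studies[, list(n_studies = .N), by = "patient_id"]
  ck <- cohort$series[, list(n_series = .N), by = "patient_id"]
  ci <- cohort$images[, list(n_images = .N), by = "patient_id"]
  out <- Reduce(function(a, b) merge(a, b, by = "patient_id", all.x = TRUE),
                list(pats, cs, ck, ci))
  for (col in c("n_studies", "n_series", "n_images"))
    out[[col]] <- ifelse(is.na(out[[col]]), 0L, out[[col]])
  out$detected <- out$n_studies > 0L
  setorder(out, patient_id)
  out[, c("patient_id", "detected", "n_studies", "n_series", "n_images")]
}

.image_rel_path <- function(images) {
  file.path(images$patient_id,
            sprintf("ST%04d", match(images$study_uid, unique(images$study_uid))),
            sprintf("SE%05d", match(images$series_uid, unique(images$series_uid))),
            sprintf("IM%05d.dcm", images$instance_number))
}

.extended_attrs <- function(i, cohort, img) {
  # deterministic device/protocol attributes, present only in full files
  h <- (nchar(img$sop_uid) + i) %% length(.MANUFACTURERS) + 1L
  pat <- cohort$patients[match(img$patient_id, cohort$patients$patient_id), ]
  ser <- cohort$series[match(img$series_uid, cohort$series$series_uid), ]
  list(
    Manufacturer = .MANUFACTURERS[h],
    ManufacturerModelName = .MODELS[h],
    StationName = sprintf("ST%02d", h),
    DeviceSerialNumber = sprintf("SN%06d", h * 1171L),
    SoftwareVersions = "syn1.0",
    ProtocolName = paste0(img$modality, "_", ser$body_part),
    BodyPartExamined = ser$body_part,
    InstitutionName = "Synthetic University Hospital",
    InstitutionAddress = "1 Example Street, Synthville",
    PatientName = pat$patient_name,
    PatientBirthDate = pat$birth_date,
    PatientSex = pat$sex,
    PatientAddress = "12 Sample Road, Synthville",
    OtherPatientIDs = paste0("HIS-", substr(img$patient_id, 4, 9)),
    ReferringPhysicianName = "REFERRER^RITA",
    OperatorsName = "OPERATOR^OTTO"
  )
}

#' Generate a synthetic PACS tree on disk
#'
#' Samples a cohort index with [sample_cohort()] and materializes it:
#' one DICOM Part 10 file per image (full header including extended
#' device/patient attributes and pixel payload), a plain-text radiology
#' report per flagged study under `reports/<AccessionNumber>.txt`, and a
#' JSON index sidecar. A fraction `inconsistency_rate` of image files
#' carries a `SeriesInstanceUID` in the file header that disagrees with
#' the index, emulating externally imported DICOM files.
#'
#' @param spec A `cohort_spec`.
#' @param out_dir Output directory (created if needed).
#' @param cohort Optionally a pre-sampled `pacs_cohort` for `spec`.
#' @return An object of class `pacs_tree`: list with `root`, `cohort`,
#'   and the per-image `files` table.
#' @export
gen_cohort <- function(spec, out_dir, cohort = NULL) {
  validate_cohort_spec(spec)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  if (is.null(cohort)) cohort <- sample_cohort(spec)
  img <- cohort$images
  rel <- if (nrow(img)) .image_rel_path(img) else character()

  if (nrow(img)) {
    for (d in unique(dirname(file.path(out_dir, rel))))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
    st_idx <- match(img$study_uid, cohort$studies$study_uid)
    se_idx <- match(img$series_uid, cohort$series$series_uid)
    for (i in seq_len(nrow(img))) {
      row <- img[i, ]
      st <- cohort$studies[st_idx[i], ]
      se <- cohort$series[se_idx[i], ]
      side <- row$side_px
      # deterministic pixel payload: smooth gradient + seeded noise
      pix_seed <- (abs(spec$seed) + 7919 * i) %% 2147483647
      pixel <- .with_seed(pix_seed, {
        g <- outer(seq_len(side), seq_len(side), function(a, b)
          (a + b) / (2 * side))
        v <- pmin(255L, pmax(0L, as.integer(g * 200 +
          stats::runif(side * side, 0, 55))))
        as.raw(v)
      })
      hdr_series_uid <- if (row$inconsistent) paste0(row$series_uid, ".999")
                        else row$series_uid
      attrs <- c(list(
        PatientID = row$patient_id,
        StudyInstanceUID = row$study_uid,
        SeriesInstanceUID = hdr_series_uid,
        SOPInstanceUID = row$sop_uid,
        StudyDate = st$study_date, StudyTime = st$study_time,
        StudyDescription = st$study_description,
        SeriesDescription = se$series_description,
        SeriesNumber = se$series_number,
        Modality = row$modality,
        AccessionNumber = st$accession_number,
        InstanceNumber = row$instance_number,
        Rows = side, Columns = side, BitsAllocated = 8L, BitsStored = 8L,
        HighBit = 7L, PixelRepresentation = 0L, SamplesPerPixel = 1L,
        PhotometricInterpretation = "MONOCHROME2",
        WindowCenter = 127, WindowWidth = 255
      ), .extended_attrs(i, cohort, row))
      dcm_write(file.path(out_dir, rel[i]), attrs, pixel = pixel)
    }
  }

  rep_studies <- cohort$studies[cohort$studies$has_report, ]
  if (nrow(rep_studies)) {
    dir.create(file.path(out_dir, "reports"), showWarnings = FALSE)
    for (i in seq_len(nrow(rep_studies))) {
      st <- rep_studies[i, ]
      writeLines(c(
        paste0("Accession: ", st$accession_number),
        paste0("Study: ", st$study_description),
        paste0("Date: ", st$study_date),
        "Findings: synthetic narrative report for linkage testing.",
        "Impression: no real clinical content."
      ), file.path(out_dir, "reports", paste0(st$accession_number, ".txt")))
    }
  }

  files <- data.table(sop_uid = img$sop_uid, path = rel)
  idx <- list(spec = unclass(cohort$spec),
              patients = cohort$patients, studies = cohort$studies,
              series = cohort$series, images = cohort$images, files = files)
  jsonlite::write_json(idx, file.path(out_dir, "index.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       Date = "ISO8601")
  structure(list(root = normalizePath(out_dir), cohort = cohort, files = files),
            class = "pacs_tree")
}

#' Load a previously generated PACS tree from its index sidecar
#'
#' @param root Directory previously passed to [gen_cohort()].
#' @return A `pacs_tree`.
#' @export
load_pacs_tree <- function(root) {
  idx_path <- file.path(root, "index.json")
  if (!file.exists(idx_path)) stop("no index.json under ", root)
  idx <- jsonlite::read_json(idx_path, simplifyVector = TRUE)
  spec <- idx$spec
  spec$date_range <- as.Date(spec$date_range)
  spec$modality_weights <- unlist(spec$modality_weights)
  spec <- structure(spec, class = "cohort_spec")
  tabs <- lapply(idx[c("patients", "studies", "series", "images")], function(x) {
    dt <- as.data.table(x)
    if (nrow(dt) == 0L) dt else dt
  })
  cohort <- structure(c(list(spec = spec), tabs), class = "pacs_cohort")
  files <- as.data.table(idx$files)
  structure(list(root = normalizePath(root), cohort = cohort, files = files),
            class = "pacs_tree")
}

#' Content digest of a generated tree
#'
#' MD5 over the sorted relative paths and per-file MD5 sums of every
#' file under the tree root; equal digests mean byte-identical trees.
#'
#' @param tree A `pacs_tree` (or a root directory path).
#' @return Character scalar digest.
#' @export
tree_digest <- function(tree) {
  root <- if (inherits(tree, "pacs_tree")) tree$root else tree
  fl <- sort(list.files(root, recursive = TRUE, full.names = FALSE))
  sums <- unname(tools::md5sum(file.path(root, fl)))
  digest::digest(paste(fl, sums, collapse = "\n"), algo = "md5", serialize = FALSE)
}

#' @export
print.pacs_cohort <- function(x, ...) {
  cat("<pacs_cohort>", nrow(x$patients), "patients,",
      nrow(x$studies), "studies,", nrow(x$series), "series,",
      nrow(x$images), "images\n")
  invisible(x)
}

#' @export
print.pacs_tree <- function(x, ...) {
  cat("<pacs_tree>", x$root, "\n")
  print(x$cohort)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Query/retrieve provider contract

#' In-process query/retrieve provider over a generated tree
#'
#' Returns the provider contract consumed by the query/retrieve client:
#' `find(level, filters)` answers from the PACS index and returns only
#' the restricted header set, and `retrieve(sop_uids)` reads the full
#' Part 10 files (including extended attributes and any identifier
#' inconsistencies present in the file headers). The same contract can
#' be implemented by an adapter to a real networked DICOM server without
#' changing callers.
#'
#' @param tree A `pacs_tree`.
#' @return Object of class `qr_provider` with elements `find`,
#'   `retrieve` and `root`.
#' @export
qr_provider <- function(tree) {
  stopifnot(inherits(tree, "pacs_tree"))
  cohort <- tree$cohort
  img <- merge(cohort$images,
               cohort$studies[, c("study_uid", "accession_number", "study_date",
                                  "study_time", "study_description")],
               by = "study_uid", sort = FALSE)
  img <- merge(img, cohort$series[, c("series_uid", "series_number",
                                      "series_description")],
               by = "series_uid", sort = FALSE)
  setorder(img, patient_id, study_uid, series_uid, instance_number)
  path_of <- setNames(tree$files$path, tree$files$sop_uid)

  apply_filters <- function(d, f) {
    keep <- rep(TRUE, nrow(d))
    if (!is.null(f$patient_ids)) keep <- keep & d$patient_id %in% f$patient_ids
    if (!is.null(f$accession_numbers))
      keep <- keep & d$accession_number %in% f$accession_numbers
    if (!is.null(f$modalities)) keep <- keep & d$modality %in% f$modalities
    if (!is.null(f$instance_uids))
      keep <- keep & (d$study_uid %in% f$instance_uids |
                      d$series_uid %in% f$instance_uids |
                      d$sop_uid %in% f$instance_uids)
    if (!is.null(f$time_from)) keep <- keep & d$study_date >= f$time_from
    if (!is.null(f$time_to)) keep <- keep & d$study_date < f$time_to
    d[keep, ]
  }

  find <- function(level, filters = list()) {
    d <- apply_filters(img, filters)
    if (level == "image") {
      out <- d[, c("patient_id", "study_uid", "series_uid", "sop_uid",
                   "instance_number", "modality", "accession_number",
                   "study_date", "study_time", "study_description",
                   "series_description")]
      setnames_basic(out)
    } else if (level == "series") {
      out <- d[, list(InstanceNumber = NA_integer_,
                      Modality = modality[1L],
                      AccessionNumber = accession_number[1L],
                      StudyDate = study_date[1L], StudyTime = study_time[1L],
                      StudyDescription = study_description[1L],
                      SeriesDescription = series_description[1L],
                      NumberOfStudyRelatedInstances = .N),
               by = list(PatientID = patient_id, StudyInstanceUID = study_uid,
                         SeriesInstanceUID = series_uid)]
      out$NumberOfStudyRelatedInstances <- NULL
      out$InstanceNumber <- NULL
      out
    } else if (level == "study") {
      out <- d[, list(AccessionNumber = accession_number[1L],
                      StudyDate = study_date[1L], StudyTime = study_time[1L],
                      StudyDescription = study_description[1L],
                      NumberOfStudyRelatedSeries = length(unique(series_uid)),
                      NumberOfStudyRelatedInstances = .N),
               by = list(PatientID = patient_id, StudyInstanceUID = study_uid)]
      out
    } else if (level == "patient") {
      d[, list(n = .N), by = list(PatientID = patient_id)][, list(PatientID)]
    } else stop("unknown query level: ", level)
  }

  retrieve <- function(sop_uids) {
    found <- sop_uids %in% names(path_of)
    records <- lapply(sop_uids[found], function(u) {
      p <- file.path(tree$root, path_of[[u]])
      ds <- dcm_read(p, include_pixel = TRUE)
      i <- match(u, img$sop_uid)
      list(sop_uid = u, patient_id = img$patient_id[i],
           study_uid = img$study_uid[i], series_uid = img$series_uid[i],
           attrs = ds$attrs, pixel = ds$pixel,
           payload_bytes = as.numeric(file.info(p)$size),
           path = p)
    })
    list(records = records, not_found = sop_uids[!found])
  }

  structure(list(find = find, retrieve = retrieve, root = tree$root,
                 n_images = nrow(img)),
            class = "qr_provider")
}

setnames_basic <- function(d) {
  map <- c(patient_id = "PatientID", study_uid = "StudyInstanceUID",
           series_uid = "SeriesInstanceUID", sop_uid = "SOPInstanceUID",
           instance_number = "InstanceNumber", modality = "Modality",
           accession_number = "AccessionNumber", study_date = "StudyDate",
           study_time = "StudyTime", study_description = "StudyDescription",
           series_description = "SeriesDescription")
  old <- intersect(names(map), names(d))
  data.table::setnames(d, old, unname(map[old]))
  d
}
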