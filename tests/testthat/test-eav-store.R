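make_import_record <- function(p = "PSN-x", st = "2.25.1", se = "2.25.1.1",
                               so = "2.25.1.1.1", acc = "ACC-1",
                               has_report = TRUE, attrs = NULL, ...) {
  c(list(patient_pseudonym = p, study_uid = st, series_uid = se, sop_uid = so,
         accession_pseudonym = acc, has_report = has_report,
         attrs = attrs %||% list(Modality = "CT", StudyDescription = "CT THORAX",
                                 InstanceNumber = 1L, StudyDate = "20160101")),
    list(...))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("group identifiers separate the naive-concatenation collision class", {
  a <- make_group_id("A|B", "C", "D")
  b <- make_group_id("A", "B|C", "D")
  expect_false(a == b)
  expect_identical(make_group_id("s", "e", "i"), make_group_id("s", "e", "i"))
  expect_match(a, "^[0-9a-f]{16}$")
  expect_error(make_group_id("", "x", "y"), "non-empty")
  expect_error(make_group_id("x", NA, "y"), "non-empty")
  # uniqueness over many random distinct triples
  n <- 10000L
  ids <- make_group_id(sprintf("1.2.%d", seq_len(n)),
                       sprintf("1.3.%d", (seq_len(n) * 7L) %% n),
                       sprintf("1.4.%d", (seq_len(n) * 13L) %% n))
  expect_identical(length(unique(ids)), n)
})

test_that("images sharing an accession with a report link to one document", {
  store <- new_store()
  on.exit(eav_close(store))
  recs <- lapply(1:3, function(i)
    make_import_record(so = paste0("2.25.1.1.", i)))
  s <- import_metadata(store, recs)
  expect_identical(s$inserted, 3L)
  expect_identical(s$linked, 3L)
  g <- eav_groups(store)
  expect_identical(nrow(g), 3L)
  expect_identical(unique(g$document_id), "RPT-ACC-1")
  d <- eav_documents(store)
  expect_identical(d$kind, "report")
  expect_identical(d$accession_pseudonym, "ACC-1")
  # linkage soundness: the linked document carries the group's accession
  expect_true(all(g$document_id == paste0("RPT-", d$accession_pseudonym)))
})

test_that("re-importing the same image updates instead of duplicating", {
  store <- new_store()
  on.exit(eav_close(store))
  r <- make_import_record()
  s1 <- import_metadata(store, list(r))
  expect_identical(c(s1$inserted, s1$updated), c(1L, 0L))
  r$attrs$StudyDescription <- "CT THORAX REVISED"
  s2 <- import_metadata(store, list(r))
  expect_identical(c(s2$inserted, s2$updated), c(0L, 1L))
  expect_identical(n_groups(store), 1L)
  rows <- eav_rows(store)
  expect_identical(rows$value_text[rows$attribute == "dicom.StudyDescription"],
                   "CT THORAX REVISED")
  expect_identical(sum(rows$attribute == "dicom.StudyDescription"), 1L)
})

test_that("records with mismatched hierarchy identifiers are quarantined, import continues", {
  store <- new_store()
  on.exit(eav_close(store))
  good <- make_import_record()
  bad <- make_import_record(so = "2.25.1.1.9",
                            header_series_uid = "2.25.9.9")
  s <- import_metadata(store, list(bad, good))
  expect_identical(s$quarantined, 1L)
  expect_identical(s$inserted, 1L)
  q <- quarantine_log(store)
  expect_identical(nrow(q), 1L)
  expect_match(q$reason, "identifier_mismatch:series_uid")
  expect_identical(n_groups(store), 1L)   # the bad record left no group
})

test_that("unlinked studies get a synthetic imaging document per study", {
  store <- new_store()
  on.exit(eav_close(store))
  recs <- list(make_import_record(has_report = FALSE, so = "2.25.1.1.1"),
               make_import_record(has_report = FALSE, so = "2.25.1.1.2"),
               make_import_record(has_report = FALSE, st = "2.25.2",
                                  se = "2.25.2.1", so = "2.25.2.1.1"))
  s <- import_metadata(store, recs)
  expect_identical(s$unlinked, 3L)
  d <- eav_documents(store)
  expect_identical(sort(unique(d$kind)), "imaging_study")
  expect_identical(nrow(d), 2L)   # one document per study
})

test_that("multi-valued attributes become one row per value with index suffixes", {
  store <- new_store()
  on.exit(eav_close(store))
  r <- make_import_record(attrs = list(Modality = "CT",
                                       WindowCenter = c(40, 400)))
  import_metadata(store, list(r))
  rows <- eav_rows(store)
  wc <- rows[grepl("^dicom.WindowCenter", rows$attribute), ]
  expect_setequal(wc$attribute, c("dicom.WindowCenter", "dicom.WindowCenter[2]"))
  expect_setequal(wc$value_num, c(40, 400))
})

test_that("warehouse queries match a brute-force scan and validate attributes", {
  store <- new_store()
  on.exit(eav_close(store))
  # 20 patients; modality and description assigned cyclically, one image each
  set.seed(5)
  pats <- sprintf("PSN-%04d", 1:20)
  mods <- rep(c("CT", "CR", "MR", "US"), 5)
  desc <- ifelse(seq_len(20) %% 5 <= 1, paste(mods, "THORAX"),
                 paste(mods, "HEAD"))
  recs <- lapply(1:20, function(i)
    make_import_record(p = pats[i], st = paste0("2.25.s", i),
                       se = paste0("2.25.s", i, ".1"),
                       so = paste0("2.25.s", i, ".1.1"),
                       acc = paste0("ACC-", i), has_report = i %% 2 == 0,
                       attrs = list(Modality = mods[i],
                                    StudyDescription = desc[i],
                                    InstanceNumber = i,
                                    StudyDate = sprintf("201601%02d", i))))
  import_metadata(store, recs)
  # oracle: plain R filter over the construction
  expected <- sort(pats[mods == "CT" & grepl("thorax", desc, ignore.case = TRUE)])
  got <- eav_query(store, list(p_eq("dicom.Modality", "CT"),
                               p_contains("dicom.StudyDescription", "thorax")))
  expect_identical(as.character(got), expected)
  # empty predicate list: every patient with any row
  expect_identical(as.character(eav_query(store)), sort(pats))
  # unsatisfiable conjunction
  expect_length(eav_query(store, list(p_eq("dicom.Modality", "CT"),
                                      p_eq("dicom.Modality", "XX"))), 0L)
  # numeric comparison and date range against the oracle
  expect_identical(as.character(eav_query(store,
    list(p_cmp("dicom.InstanceNumber", ">", 15)))), sort(pats[16:20]))
  expect_identical(as.character(eav_query(store,
    list(p_date_range("dicom.StudyDate", "2016-01-03", "2016-01-06")))),
    sort(pats[3:5]))
  # existence / non-existence
  expect_identical(as.character(eav_query(store,
    list(p_exists("dicom.Modality")))), sort(pats))
  expect_length(eav_query(store, list(p_not_exists("dicom.Modality"))), 0L)
  # unknown attribute: validation error listing the catalog
  expect_error(eav_query(store, list(p_eq("dicom.Nope", 1))),
               "dicom.Modality")
})

test_that("catalog and CSV exports round-trip the stored content", {
  store <- new_store()
  on.exit(eav_close(store))
  import_metadata(store, list(make_import_record()))
  js <- jsonlite::fromJSON(catalog_json(store))
  expect_true("dicom.Modality" %in% js$attribute)
  expect_identical(js$value_type[js$attribute == "dicom.InstanceNumber"],
                   "number")
  expect_identical(js$value_type[js$attribute == "dicom.StudyDate"], "date")
  f <- tempfile(fileext = ".csv")
  eav_export_csv(store, f)
  back <- utils::read.csv(f)
  expect_identical(nrow(back), nrow(eav_rows(store)))
})
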