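## Series-level DICOM validation: declarative attribute rules, uniqueness,
## missing-slice gaps, private-tag notes, and a pass/fail verdict.

.finding_codes <- c("MISSING_TYPE1", "EMPTY_TYPE1", "EMPTY_TYPE2",
                    "MISSING_TYPE2", "MISSING_SLICE", "NON_UNIQUE",
                    "DUPLICATE_LOCATION", "MISSING_GEOMETRY",
                    "CORRUPT_FILE", "PRIVATE_TAG_NOTE", "TYPE3_NOTE")

finding <- function(code, severity, message, tag = NA_character_,
                    sop_instance_uid = NA_character_) {
  stopifnot(code %in% .finding_codes)
  tibble::new_tibble(
    list(code = code, severity = severity, tag = tag,
         sop_instance_uid = sop_instance_uid %||% NA_character_,
         message = message),
    nrow = length(code))
}

.empty_findings <- tibble::tibble(
  code = character(), severity = character(), tag = character(),
  sop_instance_uid = character(), message = character())

no_findings <- function() .empty_findings

## Severity policy. The curation workflow is stricter than the DICOM
## standard: under the "strict" profile an empty type-2 attribute fails the
## series (anonymized archives routinely blank type-2 values, and such series
## are discarded); "lenient" downgrades EMPTY_TYPE2 to a warning, which is
## the standard-conformant reading.
finding_severity <- function(code, profile) {
  fail_codes <- c("MISSING_TYPE1", "EMPTY_TYPE1", "EMPTY_TYPE2",
                  "MISSING_TYPE2", "MISSING_SLICE", "NON_UNIQUE",
                  "MISSING_GEOMETRY", "CORRUPT_FILE")
  if (code %in% fail_codes) {
    if (code == "EMPTY_TYPE2" && profile == "lenient") "warn" else "fail"
  } else if (code == "DUPLICATE_LOCATION") {
    "warn"
  } else {
    "info"
  }
}

#' Validate one instance against one registry rule
#'
#' Applies a type-class rule to a single instance: type 1 must be present and
#' non-empty, type 2 present (emptiness failing only under the strict
#' profile), type 3 optional (optionally noted when present); `1C`/`2C` rules
#' are evaluated only when their registered condition predicate fires, and
#' degrade to an info note when the condition is unset or unknown.
#'
#' @param rule One registry row (see [default_registry()]).
#' @param inst A `dicom_instance`.
#' @param profile `"strict"` (default) or `"lenient"`.
#' @return A findings tibble (zero rows when conformant).
#' @export
validate_element <- function(rule, inst, profile = c("strict", "lenient")) {
  profile <- match.arg(profile)
  tc <- rule$type_class
  sop <- dcm_chr1(inst, "SOPInstanceUID")
  if (tc %in% c("1C", "2C")) {
    pred <- if (!is.na(rule$condition)) .registry_conditions[[rule$condition]] else NULL
    if (is.null(pred)) {
      return(finding("TYPE3_NOTE", "info",
                     sprintf("conditional rule for %s (%s) not evaluated: no registered condition",
                             rule$keyword, rule$tag),
                     tag = rule$tag, sop_instance_uid = sop))
    }
    if (!isTRUE(pred(inst))) return(no_findings())
    tc <- substr(tc, 1, 1)  # condition fired: apply as unconditional class
  }
  present <- dcm_present(inst, rule$tag)
  empty <- present && dcm_empty(inst, rule$tag)
  if (tc == "1") {
    if (!present) {
      return(finding("MISSING_TYPE1", finding_severity("MISSING_TYPE1", profile),
                     sprintf("type 1 attribute %s (%s) absent", rule$keyword, rule$tag),
                     tag = rule$tag, sop_instance_uid = sop))
    }
    if (empty) {
      return(finding("EMPTY_TYPE1", finding_severity("EMPTY_TYPE1", profile),
                     sprintf("type 1 attribute %s (%s) present but empty",
                             rule$keyword, rule$tag),
                     tag = rule$tag, sop_instance_uid = sop))
    }
  } else if (tc == "2") {
    if (!present) {
      return(finding("MISSING_TYPE2", finding_severity("MISSING_TYPE2", profile),
                     sprintf("type 2 attribute %s (%s) absent", rule$keyword, rule$tag),
                     tag = rule$tag, sop_instance_uid = sop))
    }
    if (empty) {
      return(finding("EMPTY_TYPE2", finding_severity("EMPTY_TYPE2", profile),
                     sprintf("type 2 attribute %s (%s) empty without any value",
                             rule$keyword, rule$tag),
                     tag = rule$tag, sop_instance_uid = sop))
    }
  } else if (tc == "3") {
    if (present && isTRUE(rule$note_presence)) {
      return(finding("TYPE3_NOTE", "info",
                     sprintf("type 3 attribute %s (%s) present", rule$keyword, rule$tag),
                     tag = rule$tag, sop_instance_uid = sop))
    }
  }
  no_findings()
}

#' Check value uniqueness across a series
#'
#' Tags registered at series scope (series UID, slice thickness, kVp, patient
#' position, ...) must carry one value across all instances; tags at instance
#' scope (SOP Instance UID) must be distinct per instance. Effective slice
#' locations duplicated within 1e-3 mm are reported as
#' `DUPLICATE_LOCATION` (warning severity: a duplicate position alone does
#' not prove a broken series, but it deserves eyes).
#'
#' @param series A `series_record` (grouped; sorted or not).
#' @param registry Registry tibble; defaults to [default_registry()].
#' @param profile Severity profile.
#' @return A findings tibble.
#' @export
check_uniqueness <- function(series, registry = default_registry(),
                             profile = c("strict", "lenient")) {
  profile <- match.arg(profile)
  insts <- series$instances
  findings <- list(no_findings())
  if (length(insts) == 0) return(no_findings())
  rules <- dplyr::filter(registry, .data$enabled, .data$uniqueness != "none")
  for (i in seq_len(nrow(rules))) {
    rule <- rules[i, ]
    vals <- vapply(insts, function(x) {
      v <- dcm_value(x, rule$tag)
      if (is.null(v) || length(v) == 0) NA_character_ else
        paste(as.character(v), collapse = "\\")
    }, character(1))
    seen <- vals[!is.na(vals)]
    if (rule$uniqueness == "series") {
      if (length(unique(seen)) > 1) {
        findings[[length(findings) + 1L]] <- finding(
          "NON_UNIQUE", finding_severity("NON_UNIQUE", profile),
          sprintf("%s (%s) not constant across series: %s", rule$keyword,
                  rule$tag, paste(unique(seen), collapse = " / ")),
          tag = rule$tag)
      }
    } else if (rule$uniqueness == "instance") {
      dup <- unique(seen[duplicated(seen)])
      if (length(dup) > 0) {
        findings[[length(findings) + 1L]] <- finding(
          "NON_UNIQUE", finding_severity("NON_UNIQUE", profile),
          sprintf("%s (%s) duplicated across instances: %s", rule$keyword,
                  rule$tag, paste(dup, collapse = ", ")),
          tag = rule$tag)
      }
    }
  }
  ## per-instance-unique effective location
  locs <- vapply(insts, function(x) {
    tryCatch(effective_slice_location(x),
             ctcurate_missing_geometry = function(e) NA_real_)
  }, numeric(1))
  q <- round(locs[!is.na(locs)] / .loc_tol)
  if (anyDuplicated(q)) {
    dup_locs <- unique(q[duplicated(q)]) * .loc_tol
    findings[[length(findings) + 1L]] <- finding(
      "DUPLICATE_LOCATION", finding_severity("DUPLICATE_LOCATION", profile),
      sprintf("duplicate effective slice location(s): %s",
              paste(format(dup_locs), collapse = ", ")))
  }
  dplyr::bind_rows(findings)
}

#' Detect missing slices from a sorted location list
#'
#' Infers the inter-slice spacing as the median of successive location
#' differences and flags every difference exceeding `factor` times that
#' spacing as a gap, estimating `round(diff / spacing) - 1` missing slices.
#' Fewer than 3 locations cannot anchor a spacing estimate and yield an
#' indeterminate report.
#'
#' @param locations Numeric vector of slice locations (mm), ascending.
#' @param factor Gap threshold as a multiple of the inferred spacing
#'   (default 1.5).
#' @return A `gap_report`: list with `inferred_spacing`, `gaps` (tibble of
#'   `location_before`, `location_after`, `estimated_missing`) and
#'   `indeterminate`.
#' @examples
#' detect_missing_slices(c(0, 2.5, 7.5, 10))  # one gap, one missing slice
#' @export
detect_missing_slices <- function(locations, factor = 1.5) {
  empty_gaps <- tibble::tibble(location_before = numeric(),
                               location_after = numeric(),
                               estimated_missing = integer())
  if (length(locations) < 3) {
    return(structure(list(inferred_spacing = NA_real_, gaps = empty_gaps,
                          indeterminate = TRUE), class = "gap_report"))
  }
  if (is.unsorted(locations, strictly = FALSE)) {
    abort("locations must be sorted ascending", class = "ctcurate_geometry_error")
  }
  d <- diff(locations)
  spacing <- stats::median(d)
  gaps <- empty_gaps
  if (spacing > .loc_tol) {
    idx <- which(d > factor * spacing + .loc_tol)
    if (length(idx)) {
      gaps <- tibble::tibble(
        location_before = locations[idx],
        location_after = locations[idx + 1L],
        estimated_missing = pmax(1L, as.integer(round(d[idx] / spacing)) - 1L)
      )
    }
  }
  structure(list(inferred_spacing = spacing, gaps = gaps,
                 indeterminate = FALSE), class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  if (x$indeterminate) {
    cat("<gap_report> indeterminate (fewer than 3 slices)\n")
  } else {
    cat(sprintf("<gap_report> inferred spacing %.4g mm, %d gap(s)\n",
                x$inferred_spacing, nrow(x$gaps)))
    if (nrow(x$gaps)) print(x$gaps)
  }
  invisible(x)
}

#' Note recognized vendor private tags
#'
#' Scans odd-numbered (private) groups; when a private-creator element
#' (gggg,0010) matches a registered vendor creator, every element of that
#' block yields an informational finding recording presence and VR only.
#' Unknown creators are ignored. Never affects the verdict.
#'
#' @param series A `series_record`.
#' @param vendors Vendor registry tibble (see [default_vendor_registry()]).
#' @return A findings tibble of `PRIVATE_TAG_NOTE` info rows.
#' @export
note_private_tags <- function(series, vendors = default_vendor_registry()) {
  findings <- list(no_findings())
  for (inst in series$instances) {
    sop <- dcm_chr1(inst, "SOPInstanceUID")
    els <- inst$elements
    groups <- vapply(els, function(e) e$group, integer(1))
    priv <- unique(groups[groups %% 2L == 1L & groups > 0x0008L])
    for (g in priv) {
      creator_el <- els[[tag_key(g, 0x0010L)]]
      creator <- if (!is.null(creator_el) && length(creator_el$value)) {
        as.character(creator_el$value[1])
      } else NA_character_
      hit <- match(creator, vendors$creator)
      if (is.na(hit)) next
      in_group <- els[groups == g]
      for (e in in_group) {
        findings[[length(findings) + 1L]] <- finding(
          "PRIVATE_TAG_NOTE", "info",
          sprintf("vendor (%s) private tag %s, VR %s", vendors$vendor[hit],
                  tag_key(e$group, e$element), e$vr),
          tag = tag_key(e$group, e$element), sop_instance_uid = sop)
      }
    }
  }
  dplyr::bind_rows(findings)
}

#' Validate a CT series
#'
#' Runs the full conformance screen on one series: sorts instances by
#' effective slice location (falling back from Slice Location to the Image
#' Position z component), applies every enabled registry rule to every
#' instance, checks series/instance uniqueness, detects missing-slice gaps,
#' and notes recognized vendor private tags. The verdict is `"fail"` iff at
#' least one finding carries severity `fail`.
#'
#' @param x A `series_record` or a directory of slice files (read via
#'   [read_series()]; unreadable files become `CORRUPT_FILE` findings).
#' @param registry Rule registry tibble; defaults to [default_registry()].
#' @param profile `"strict"` (default; empty type-2 attributes fail, the
#'   curation behavior) or `"lenient"` (standard-conformant: empty type-2
#'   warns).
#' @param vendors Vendor private-tag registry.
#' @param gap_factor Gap threshold multiple for [detect_missing_slices()].
#' @return A `validation_report`: list with `series_uid`, `verdict`
#'   (`"pass"`/`"fail"`), `findings` tibble, `counts` (per-code tibble),
#'   `profile`, `n_instances`, `gap_report`.
#' @seealso [tidy()] and [glance()] methods, [report_to_json()]
#' @export
validate_series <- function(x, registry = default_registry(),
                            profile = c("strict", "lenient"),
                            vendors = default_vendor_registry(),
                            gap_factor = 1.5) {
  profile <- match.arg(profile)
  check_registry(registry)
  findings <- list(no_findings())
  if (is.character(x) && length(x) == 1) {
    x <- read_series(x, on_error = "collect")
    errs <- attr(x, "read_errors")
    if (!is.null(errs) && nrow(errs)) {
      for (i in seq_len(nrow(errs))) {
        findings[[length(findings) + 1L]] <- finding(
          "CORRUPT_FILE", finding_severity("CORRUPT_FILE", profile),
          sprintf("unreadable instance %s: %s", basename(errs$path[i]),
                  errs$message[i]))
      }
    }
  }
  if (!inherits(x, "series_record")) {
    abort("x must be a series_record or a directory path",
          class = "ctcurate_io_error")
  }
  series <- x
  insts <- series$instances

  ## geometry: effective locations, with missing geometry as findings
  locs <- rep(NA_real_, length(insts))
  for (i in seq_along(insts)) {
    locs[i] <- tryCatch(effective_slice_location(insts[[i]]),
                        ctcurate_missing_geometry = function(e) NA_real_)
    if (is.na(locs[i])) {
      findings[[length(findings) + 1L]] <- finding(
        "MISSING_GEOMETRY", finding_severity("MISSING_GEOMETRY", profile),
        sprintf("instance %s has neither (0020,1041) nor (0020,0032)",
                dcm_chr1(insts[[i]], "SOPInstanceUID") %||% "<no SOP UID>"),
        sop_instance_uid = dcm_chr1(insts[[i]], "SOPInstanceUID"))
    }
  }
  sortable <- !anyNA(locs)
  if (sortable && length(insts)) series <- sort_instances(series)

  ## element rules over every instance (rules as plain lists: hot path)
  rules <- dplyr::filter(registry, .data$enabled)
  rule_list <- lapply(seq_len(nrow(rules)), function(i) {
    lapply(rules, function(col) col[i])
  })
  for (inst in series$instances) {
    for (rule in rule_list) {
      f <- validate_element(rule, inst, profile = profile)
      if (nrow(f)) findings[[length(findings) + 1L]] <- f
    }
  }

  findings[[length(findings) + 1L]] <-
    check_uniqueness(series, registry, profile = profile)

  gap_rep <- NULL
  if (sortable && length(insts)) {
    gap_rep <- detect_missing_slices(sort(locs), factor = gap_factor)
    if (nrow(gap_rep$gaps)) {
      for (i in seq_len(nrow(gap_rep$gaps))) {
        g <- gap_rep$gaps[i, ]
        findings[[length(findings) + 1L]] <- finding(
          "MISSING_SLICE", finding_severity("MISSING_SLICE", profile),
          sprintf("gap between %.4g and %.4g mm: ~%d missing slice(s) at spacing %.4g mm",
                  g$location_before, g$location_after, g$estimated_missing,
                  gap_rep$inferred_spacing))
      }
    }
  }

  findings[[length(findings) + 1L]] <- note_private_tags(series, vendors)

  all_findings <- dplyr::bind_rows(findings)
  ## collapse per-instance repeats of the same element finding into one row
  ## per (code, tag, sop) -- already distinct -- but keep deterministic order
  all_findings <- dplyr::arrange(all_findings, .data$code, .data$tag,
                                 .data$sop_instance_uid)
  verdict <- if (any(all_findings$severity == "fail")) "fail" else "pass"
  counts <- all_findings |>
    dplyr::count(.data$code, name = "n") |>
    dplyr::arrange(.data$code)
  structure(
    list(series_uid = series$series_uid, verdict = verdict,
         findings = all_findings, counts = counts, profile = profile,
         n_instances = length(series$instances), gap_report = gap_rep),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> series %s\n", x$series_uid))
  cat(sprintf("  profile: %s | instances: %d | verdict: %s\n",
              x$profile, x$n_instances, toupper(x$verdict)))
  if (nrow(x$counts)) {
    for (i in seq_len(nrow(x$counts))) {
      cat(sprintf("  %-18s %d\n", x$counts$code[i], x$counts$n[i]))
    }
  } else {
    cat("  no findings\n")
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' Writes the report with stable key order (series, profile, verdict,
#' counts, findings) so reports diff cleanly.
#'
#' @param report A `validation_report`.
#' @param path Output file; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    series_uid = report$series_uid,
    profile = report$profile,
    n_instances = report$n_instances,
    verdict = report$verdict,
    counts = report$counts,
    findings = report$findings
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, na = "null"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
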