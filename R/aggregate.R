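#' Aggregate Pfam-domain abundances onto KEGG Orthologies
#'
#' The Pfam-to-KO mapping is many-to-many: a domain maps to every KO whose
#' gene representatives contain it.  Each mapped domain's abundance is added
#' in full to every KO it maps to (fan-out duplicates abundance rather than
#' splitting it), so total KO abundance equals the sum over mapped domains
#' of abundance times the domain's out-degree.  Unmapped domains are
#' dropped; mapping rows naming absent domains are ignored and counted.
#'
#' @param features stations x Pfam matrix of nonnegative values.
#' @param mapping data.frame with columns `pfam_id`, `ko_id`; duplicate
#'   pairs are collapsed.
#' @return stations x KO matrix with attributes `n_pfam_mapped` (mapped
#'   domains present in the table), `n_pfam_total` (total domains in the
#'   table) and `n_ignored_pairs` (mapping rows naming absent domains).
#' @export
aggregate_to_ko <- function(features, mapping) {
  features <- as_feature_matrix(features)
  check_nonnegative(features)
  if (!all(c("pfam_id", "ko_id") %in% names(mapping)))
    stop("mapping needs columns 'pfam_id' and 'ko_id'")
  mapping <- unique(mapping[, c("pfam_id", "ko_id")])
  present <- mapping$pfam_id %in% colnames(features)
  n_ignored <- sum(!present)
  if (n_ignored > 0)
    message(sprintf("ignoring %d mapping pair(s) for domains absent from the table",
                    n_ignored))
  m <- mapping[present, , drop = FALSE]
  if (nrow(m) == 0) {
    out <- matrix(0, nrow(features), 0,
                  dimnames = list(rownames(features), character(0)))
  } else {
    # duplicate pfam columns per mapping pair, then sum within KO
    out <- t(rowsum(t(features[, m$pfam_id, drop = FALSE]), group = m$ko_id))
  }
  attr(out, "n_pfam_mapped") <- length(unique(m$pfam_id))
  attr(out, "n_pfam_total") <- ncol(features)
  attr(out, "n_ignored_pairs") <- n_ignored
  out
}

#' Regional presence/absence profile of KO abundances
#'
#' A KO is present in a region when any station of the region has abundance
#' strictly above `threshold`.
#'
#' @param ko stations x KO abundance matrix.
#' @param regions region label per station.
#' @param threshold presence threshold (default 0).
#' @return regions x KO binary (0/1) matrix.
#' @export
presence_absence_profile <- function(ko, regions, threshold = 0) {
  g <- factor(regions)
  if (length(g) != nrow(ko))
    stop("regions must give one label per station")
  pa <- (rowsum((ko > threshold) + 0, g) > 0) + 0
  pa
}

#' Export signed driver associations per KO
#'
#' For features attributed to `driver`, propagates each feature's
#' association sign through the Pfam-to-KO mapping and counts positively and
#' negatively associated domains per KO — the input table for external
#' functional-tree plotting.
#'
#' @param attr an `attribution_table`.
#' @param mapping data.frame with columns `pfam_id`, `ko_id`.
#' @param driver the driver (covariate name) to export.
#' @return data.frame with columns `ko_id`, `n_positive`, `n_negative`.
#' @export
signed_driver_export <- function(attr, mapping, driver) {
  if (!driver %in% attr$driver)
    stop(sprintf("driver '%s' not present in the attribution table", driver))
  sel <- attr[attr$driver == driver, c("feature_id", "sign")]
  m <- unique(mapping[, c("pfam_id", "ko_id")])
  m <- merge(m, sel, by.x = "pfam_id", by.y = "feature_id")
  if (nrow(m) == 0)
    return(data.frame(ko_id = character(0), n_positive = integer(0),
                      n_negative = integer(0)))
  pos <- rowsum((m$sign > 0) + 0L, m$ko_id)
  neg <- rowsum((m$sign < 0) + 0L, m$ko_id)
  data.frame(ko_id = rownames(pos),
             n_positive = as.integer(pos),
             n_negative = as.integer(neg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Integer coverage percentage
#'
#' Reporting convention for assignment coverage: `100 * n_assigned /
#' n_total` rounded to the nearest integer percent.
#'
#' @param n_assigned number of assigned items.
#' @param n_total total number of items (> 0).
#' @return integer percent.
#' @export
coverage_percent <- function(n_assigned, n_total) {
  if (!is.numeric(n_total) || n_total <= 0)
    stop("n_total must be positive")
  if (!is.numeric(n_assigned) || n_assigned < 0 || n_assigned > n_total)
    stop("n_assigned must lie in [0, n_total]")
  round(100 * n_assigned / n_total)
}
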