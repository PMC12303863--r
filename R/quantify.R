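## Per-residue roll-up of matched peptides. PSM mode counts occurrences
## weighted by each record's PSM count (weight 1 when the source had no
## PSM column); intensity/area mode first collapses duplicate observations
## of the same stripped sequence within a group (summing the quantity),
## then adds the aggregated quantity at every residue the peptide covers.

.datatable.aware <- TRUE

#' Roll matched peptides up to per-residue metric values
#'
#' @param ms A \code{MatchSet} from \code{\link{matchPeptides}}.
#' @param ps The \code{PeptideSet} the matches refer to.
#' @param metric \code{"psm"} (default), \code{"intensity"} or
#'   \code{"area"}.
#' @param group_by Character vector of condition fields defining heatmap
#'   rows (e.g. \code{"donor"}); empty for one global group.
#' @param count_mode For psm metric only: \code{"weighted"} (default,
#'   PSM-weighted occurrence count) or \code{"distinct"} (number of
#'   distinct stripped sequences covering the position).
#' @return A \code{PositionQuant}. Positions covered by no peptide are
#'   absent from the table (rendered blank/zero downstream). A peptide
#'   matching multiple sites contributes at every site.
#' @importFrom data.table data.table setorderv :=
#' @export
quantifyPositions <- function(ms, ps, metric = c("psm", "intensity", "area"),
                              group_by = character(0),
                              count_mode = c("weighted", "distinct")) {
  metric <- match.arg(metric)
  count_mode <- match.arg(count_mode)
  stopifnot(is(ms, "MatchSet"), is(ps, "PeptideSet"))
  rec <- as.data.frame(ps@records[, setdiff(colnames(ps@records), "ptm_raw"),
                                  drop = FALSE])
  miss_g <- setdiff(group_by, colnames(rec))
  if (length(miss_g))
    stop("group_by field(s) not in peptide records: ",
         paste(miss_g, collapse = ", "))
  m <- as.data.frame(ms@matches[, c("record_id", "target_id", "start",
                                    "end"), drop = FALSE])
  if (metric != "psm") {
    v <- rec[[metric]]
    if (all(is.na(v)))
      stop("metric '", metric, "' requested but the field is absent on ",
           "all records")
    if (any(!is.na(v) & v < 0))
      stop("negative ", metric, " on record ",
           rec$record_id[which(!is.na(v) & v < 0)[1]])
  }
  empty <- DataFrame(target_id = character(0), position = integer(0),
                     value = numeric(0))
  for (g in group_by) empty[[g]] <- character(0)
  empty <- empty[, c("target_id", group_by, "position", "value"),
                 drop = FALSE]
  if (!nrow(m))
    return(new("PositionQuant", quant = empty, metric = metric,
               groupBy = group_by))
  keep <- c("record_id", "stripped_sequence", "psm", "intensity", "area",
            group_by)
  dt <- data.table::data.table(merge(m, rec[, keep, drop = FALSE],
                                     by = "record_id", sort = FALSE))
  gcols <- c("target_id", group_by)
  if (metric == "psm") {
    if (count_mode == "weighted") {
      dt[, weight := ifelse(is.na(psm), 1, psm)]
      long <- dt[, .(position = seq(start, end), value = weight),
                 by = c(gcols, "record_id", "start")]
      out <- long[, .(value = sum(value)), by = c(gcols, "position")]
    } else {
      long <- dt[, .(position = seq(start, end)),
                 by = c(gcols, "stripped_sequence", "record_id", "start")]
      out <- long[, .(value = data.table::uniqueN(stripped_sequence)),
                  by = c(gcols, "position")]
    }
  } else {
    dt[, qty := get(metric)]
    n_missing <- dt[, data.table::uniqueN(record_id[is.na(qty)])]
    if (n_missing > 0)
      warning(sprintf("%d record(s) without %s contribute 0", n_missing,
                      metric))
    dt[, qty := ifelse(is.na(qty), 0, qty)]
    ## aggregated quantity per unique stripped sequence within group:
    ## each record counted once even when matched at several sites
    agg <- unique(dt[, c(gcols, "stripped_sequence", "record_id", "qty"),
                     with = FALSE])[
      , .(agg_qty = sum(qty)), by = c(gcols, "stripped_sequence")]
    sites <- unique(dt[, c(gcols, "stripped_sequence", "start", "end"),
                       with = FALSE])
    sites <- merge(sites, agg, by = c(gcols, "stripped_sequence"))
    long <- sites[, .(position = seq(start, end), value = agg_qty),
                  by = c(gcols, "stripped_sequence", "start")]
    out <- long[, .(value = sum(value)), by = c(gcols, "position")]
  }
  data.table::setorderv(out, c(gcols, "position"))
  q <- DataFrame(as.data.frame(out))
  new("PositionQuant", quant = q, metric = metric, groupBy = group_by)
}

#' Per-target, per-group coverage summary
#'
#' @param pq A \code{PositionQuant}.
#' @param targets The \code{TargetSet} (provides target lengths).
#' @param groups Optional data.frame enumerating expected
#'   (target_id, group) combinations; combinations without any covered
#'   position get a row with \code{covered = 0}.
#' @return data.frame with \code{target_id}, group columns,
#'   \code{covered} (distinct covered residues), \code{fraction}
#'   (covered / target length) and \code{max_value}.
#' @export
coverageSummary <- function(pq, targets, groups = NULL) {
  stopifnot(is(pq, "PositionQuant"), is(targets, "TargetSet"))
  q <- as.data.frame(pq@quant)
  lens <- setNames(width(targets@sequences), names(targets@sequences))
  unknown <- setdiff(q$target_id, names(lens))
  if (length(unknown))
    stop("unknown target length for: ", paste(unknown, collapse = ", "))
  gcols <- c("target_id", pq@groupBy)
  if (nrow(q)) {
    dt <- data.table::data.table(q)
    s <- dt[, .(covered = data.table::uniqueN(position),
                max_value = max(value)), by = gcols]
    s <- as.data.frame(s)
  } else {
    s <- data.frame(matrix(nrow = 0, ncol = length(gcols)))
    colnames(s) <- gcols
    s$covered <- integer(0); s$max_value <- numeric(0)
  }
  if (!is.null(groups)) {
    groups <- as.data.frame(groups)
    unknown <- setdiff(groups$target_id, names(lens))
    if (length(unknown))
      stop("unknown target length for: ", paste(unknown, collapse = ", "))
    s <- merge(groups[, gcols, drop = FALSE], s, by = gcols, all.x = TRUE)
    s$covered[is.na(s$covered)] <- 0L
    s$max_value[is.na(s$max_value)] <- 0
  }
  s$fraction <- s$covered / as.vector(lens[s$target_id])
  s[, c(gcols, "covered", "fraction", "max_value")]
}

#' Write a position quant table as long-format TSV
#'
#' Columns: target_id, group columns, position, metric, value — directly
#' consumable by external statistics tools.
#'
#' @param pq A \code{PositionQuant}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeQuantTable <- function(pq, path) {
  stopifnot(is(pq, "PositionQuant"))
  df <- as.data.frame(pq@quant)
  df$metric <- pq@metric
  df <- df[, c("target_id", pq@groupBy, "position", "metric", "value")]
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
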