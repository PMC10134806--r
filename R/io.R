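#' Read pellet-weighing records from CSV
#'
#' Expects columns `sample_id`, `dry_mg`, `wet_mg`, `od_ml`, `rho` and
#' (optionally) `beta` (default 2 mg water/mg CDW).
#'
#' @param path CSV file path.
#' @return named list of [pellet_weighing()] records.
#' @export
read_pellet_records <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "dry_mg", "wet_mg", "od_ml", "rho")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"beta" %in% names(tab)) tab$beta <- 2
  recs <- lapply(seq_len(nrow(tab)), function(i)
    pellet_weighing(tab$dry_mg[i], tab$wet_mg[i], tab$od_ml[i],
                    tab$rho[i], tab$beta[i]))
  stats::setNames(recs, tab$sample_id)
}

#' Read a batch-culture time series from CSV
#'
#' Expects columns `time_h`, `od600`, `substrate_mM`, `acetate_mM` — the
#' dialect the analysis scripts (and [simulate_batch()]-derived tables)
#' write.
#'
#' @param path CSV file path.
#' @param substrate_carbons carbon atoms per substrate molecule.
#' @param medium_label free-text label.
#' @param ... passed to [batch_series()] (e.g. `noise_tol`).
#' @return a [batch_series()].
#' @export
read_batch_series <- function(path, substrate_carbons, medium_label = "",
                              ...) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "od600", "substrate_mM", "acetate_mM")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  batch_series(tab$time_h, tab$od600, tab$substrate_mM, tab$acetate_mM,
               substrate_carbons, medium_label = medium_label, ...)
}

#' Read long-format plate curves from CSV
#'
#' Expects columns `substrate`, `replicate`, `time_h`, `od600`.
#'
#' @param path CSV file path.
#' @return list of [plate_curve()]s, one per substrate/replicate pair.
#' @export
read_plate_curves <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substrate", "replicate", "time_h", "od600")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- list()
  for (key in split(seq_len(nrow(tab)),
                    paste(tab$substrate, tab$replicate, sep = "\r"))) {
    rows <- tab[key, ]
    rows <- rows[order(rows$time_h), ]
    out[[length(out) + 1L]] <- plate_curve(rows$substrate[1], rows$time_h,
                                           rows$od600, rows$replicate[1])
  }
  out
}
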