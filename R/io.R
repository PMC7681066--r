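# Plain-text I/O: long-format peptide TSVs, phenotype TSVs, truth
# tables, configs, and the packaged reference tables.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a simulated study to a directory of TSV files
#'
#' Writes `peptides.tsv` (long format: participant_id, peptide_id,
#' protein_id, log10_abundance, imputed_flag; missing cells omitted),
#' `qc_pool.tsv`, `participants.tsv`, `truth.tsv` and `config.json`.
#'
#' @param study A `serolong_study`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ab <- study$peptides$abundance
  obs <- which(!is.na(ab), arr.ind = TRUE)
  map <- study$peptides$map
  long <- data.frame(
    participant_id = rownames(ab)[obs[, 1]],
    peptide_id = colnames(ab)[obs[, 2]],
    protein_id = map$protein_id[obs[, 2]],
    log10_abundance = ab[obs],
    imputed_flag = as.integer(study$peptides$imputed[obs]))
  long <- long[order(long$participant_id, long$peptide_id), ]
  write_tsv(long, file.path(dir, "peptides.tsv"))
  qc <- study$peptides$qc_pool
  qobs <- which(!is.na(qc), arr.ind = TRUE)
  write_tsv(data.frame(replicate_id = rownames(qc)[qobs[, 1]],
                       peptide_id = colnames(qc)[qobs[, 2]],
                       log10_abundance = qc[qobs]),
            file.path(dir, "qc_pool.tsv"))
  pt <- study$participants
  pt$site <- as.integer(as.character(pt$site))
  write_tsv(pt, file.path(dir, "participants.tsv"))
  tr <- study$truth$proteins
  write_tsv(tr, file.path(dir, "truth.tsv"))
  cfg <- study$truth$config
  if (!is.null(cfg))
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory holding `peptides.tsv`, `participants.tsv` and
#'   optionally `qc_pool.tsv`.
#' @return A list with `peptides` (`serolong_peptides`) and
#'   `participants`.
#' @export
read_study <- function(dir) {
  long <- read.delim(file.path(dir, "peptides.tsv"))
  pt <- read.delim(file.path(dir, "participants.tsv"))
  pt$site <- factor(pt$site)
  map <- unique(long[, c("peptide_id", "protein_id")])
  map <- map[order(map$peptide_id), ]
  rownames(map) <- NULL
  ab <- matrix(NA_real_, nrow(pt), nrow(map),
               dimnames = list(pt$id, map$peptide_id))
  imp <- matrix(FALSE, nrow(pt), nrow(map), dimnames = dimnames(ab))
  ij <- cbind(match(long$participant_id, pt$id),
              match(long$peptide_id, map$peptide_id))
  ab[ij] <- long$log10_abundance
  imp[ij] <- long$imputed_flag == 1
  qc <- NULL
  qf <- file.path(dir, "qc_pool.tsv")
  if (file.exists(qf)) {
    ql <- read.delim(qf)
    reps <- unique(ql$replicate_id)
    qc <- matrix(NA_real_, length(reps), nrow(map),
                 dimnames = list(reps, map$peptide_id))
    qc[cbind(match(ql$replicate_id, reps),
             match(ql$peptide_id, map$peptide_id))] <- ql$log10_abundance
  }
  list(peptides = new_peptides(ab, map, qc, imp), participants = pt)
}

#' Validate study input files
#'
#' Schema and cross-reference checks on the TSVs of a study directory:
#' required columns, finite abundances, peptides mapping to a single
#' protein, duplicate cells, and participant cross-references.
#'
#' @param dir Directory with `peptides.tsv` and `participants.tsv`.
#' @return A `data.frame` of violations (`file`, `check`, `detail`);
#'   zero rows when the inputs are well formed.
#' @export
validate_inputs <- function(dir) {
  v <- list()
  add <- function(file, check, detail)
    v[[length(v) + 1]] <<- data.frame(file = file, check = check,
                                      detail = detail)
  pf <- file.path(dir, "peptides.tsv")
  tf <- file.path(dir, "participants.tsv")
  if (!file.exists(pf)) stopf("cannot read %s", pf)
  if (!file.exists(tf)) stopf("cannot read %s", tf)
  long <- read.delim(pf)
  pt <- read.delim(tf)
  need <- c("participant_id", "peptide_id", "protein_id",
            "log10_abundance")
  miss <- setdiff(need, names(long))
  if (length(miss))
    add("peptides.tsv", "columns",
        paste("missing:", paste(miss, collapse = ",")))
  needp <- c("id", "age", "alive90th", "followup_years", "died")
  missp <- setdiff(needp, names(pt))
  if (length(missp))
    add("participants.tsv", "columns",
        paste("missing:", paste(missp, collapse = ",")))
  if (!length(miss) && !length(missp)) {
    if (any(!is.finite(long$log10_abundance)))
      add("peptides.tsv", "finite_abundance",
          sprintf("%d non-finite values",
                  sum(!is.finite(long$log10_abundance))))
    multi <- tapply(long$protein_id, long$peptide_id,
                    function(x) length(unique(x)))
    if (any(multi > 1))
      add("peptides.tsv", "unique_protein_map",
          paste("peptides with >1 protein:",
                paste(head(names(multi)[multi > 1], 5), collapse = ",")))
    dup <- duplicated(long[, c("participant_id", "peptide_id")])
    if (any(dup))
      add("peptides.tsv", "duplicate_cells",
          sprintf("%d duplicated participant x peptide cells", sum(dup)))
    orphan <- setdiff(unique(long$participant_id), pt$id)
    if (length(orphan))
      add("peptides.tsv", "participant_crossref",
          paste("ids absent from participants.tsv:",
                paste(head(orphan, 5), collapse = ",")))
    if (any(pt$followup_years <= 0))
      add("participants.tsv", "followup_positive",
          sprintf("%d rows with followup_years <= 0",
                  sum(pt$followup_years <= 0)))
    if (!all(pt$alive90th %in% c(0, 1)))
      add("participants.tsv", "label_binary",
          "alive90th outside {0,1}")
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(file = character(), check = character(),
                  detail = character())
}

#' Packaged reference table of tier-1 longevity protein associations
#'
#' The published tier-1 selection from the discovery cohort of older
#' men: 25 proteins with their peptide counts, meta-analyzed signed
#' fold changes and sign-error posterior probabilities (meta-p).
#'
#' @return A `data.frame` (gene, uniprot, n_peptides, protein_name,
#'   meta_fold, meta_p).
#' @export
longevity_reference_effects <- function() {
  read.delim(system.file("extdata", "tier1_longevity_effects.tsv",
                         package = "serolong"))
}

#' Packaged reference table of protein mortality hazard ratios
#'
#' Age-adjusted mortality hazard ratios per SD of abundance for the 25
#' longevity-associated proteins in the full discovery proteomics
#' cohort.
#'
#' @return A `data.frame` (gene, uniprot, hazard_ratio, p_value).
#' @export
mortality_reference_hrs <- function() {
  read.delim(system.file("extdata", "mortality_hazard_ratios.tsv",
                         package = "serolong"))
}
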