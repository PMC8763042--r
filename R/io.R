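#' Read and reconcile community CSV tables
#'
#' Reads the three tables a CATS analysis needs -- local abundances, species
#' traits, and meta-community mean abundances -- and aligns them by species
#' identifier. The dialect is fixed: comma separator, header row, `.`
#' decimal, UTF-8. Row order follows the abundance file. Validation
#' problems (duplicate identifiers, species missing from the trait or meta
#' table, non-numeric cells) are collected and reported in a single error.
#' Species present only in the meta table are allowed (the regional pool
#' may exceed the local community) and dropped with a warning.
#'
#' @param abundance_csv CSV with columns `species, abundance`.
#' @param traits_csv CSV with columns `species, <trait columns...>`.
#' @param meta_csv CSV with columns `species, mean_abundance`.
#' @return List with `abundance` (named numeric vector), `traits` (matrix),
#'   `prior` (a [meta_prior()]), `species` (character).
#' @export
read_community_tables <- function(abundance_csv, traits_csv, meta_csv) {
  ab <- utils::read.csv(abundance_csv, stringsAsFactors = FALSE)
  tr <- utils::read.csv(traits_csv, stringsAsFactors = FALSE)
  me <- utils::read.csv(meta_csv, stringsAsFactors = FALSE)
  problems <- character()
  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      problems <<- c(problems, sprintf("%s lacks column(s): %s", file,
                                       paste(miss, collapse = ", ")))
  }
  need(ab, c("species", "abundance"), "abundance table")
  need(tr, "species", "trait table")
  need(me, c("species", "mean_abundance"), "meta table")
  if (length(problems)) stop(paste(problems, collapse = "; "), call. = FALSE)

  for (nm in list(list(ab, "abundance table"), list(tr, "trait table"),
                  list(me, "meta table"))) {
    if (anyDuplicated(nm[[1]]$species))
      problems <- c(problems, sprintf("duplicate species ids in %s: %s",
                                      nm[[2]],
                                      paste(unique(nm[[1]]$species[
                                        duplicated(nm[[1]]$species)]),
                                        collapse = ", ")))
  }
  sp <- ab$species
  miss_tr <- setdiff(sp, tr$species)
  if (length(miss_tr))
    problems <- c(problems, paste("species missing from trait table:",
                                  paste(miss_tr, collapse = ", ")))
  miss_me <- setdiff(sp, me$species)
  if (length(miss_me))
    problems <- c(problems, paste("species missing from meta table:",
                                  paste(miss_me, collapse = ", ")))
  tr_num <- tr[setdiff(names(tr), "species")]
  bad_num <- names(tr_num)[!vapply(tr_num, is.numeric, logical(1))]
  if (length(bad_num))
    problems <- c(problems, paste("non-numeric trait column(s):",
                                  paste(bad_num, collapse = ", ")))
  if (!is.numeric(ab$abundance))
    problems <- c(problems, "non-numeric abundance column")
  if (!is.numeric(me$mean_abundance))
    problems <- c(problems, "non-numeric mean_abundance column")
  if (length(problems))
    stop(paste(problems, collapse = "; "), call. = FALSE)

  extra <- setdiff(me$species, sp)
  if (length(extra))
    warning("meta table covers ", length(extra),
            " species absent locally; dropped: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ...", call. = FALSE)

  y <- stats::setNames(ab$abundance, sp)
  tmat <- as.matrix(tr_num[match(sp, tr$species), , drop = FALSE])
  rownames(tmat) <- sp
  mvec <- me$mean_abundance[match(sp, me$species)]
  list(abundance = y, traits = tmat,
       prior = meta_prior(mvec, sp), species = sp)
}

#' End-to-end variation partitioning from CSV inputs
#'
#' Reads the community tables, runs [partition_variation()], and (when
#' `out` is given) writes the partition JSON. One structured log line is
#' emitted per fitted model via `message()`.
#'
#' @inheritParams read_community_tables
#' @param family,link,adjusted,fallback Passed to [partition_variation()].
#' @param out Optional path for the partition JSON.
#' @return The `"cats_partition"`, invisibly when `out` is written.
#' @export
run_partition <- function(abundance_csv, traits_csv, meta_csv,
                          family = "poisson", link = "log", adjusted = TRUE,
                          fallback = "error", out = NULL) {
  tabs <- read_community_tables(abundance_csv, traits_csv, meta_csv)
  part <- partition_variation(tabs$abundance, tabs$traits, tabs$prior,
                              family = family, link = link,
                              adjusted = adjusted, fallback = fallback)
  for (nm in c("both", "traits", "offset")) {
    f <- part$fits[[nm]]
    message(sprintf(
      "model=%s family=%s link=%s k=%d loglik=%.4f deviance=%.4f converged=%s",
      nm, f$family$name, f$link, f$k, f$loglik, f$deviance, f$converged))
  }
  if (!is.null(out)) {
    partition_json(part, out)
    return(invisible(part))
  }
  part
}

#' Write a simulated community as the CSV tables the readers expect
#'
#' @param sim Output of [simulate_selection_community()].
#' @param dir Directory for `abundance.csv`, `traits.csv`, `meta.csv`.
#' @return The three file paths, invisibly.
#' @export
write_community_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- sim$prior$species
  paths <- file.path(dir, c("abundance.csv", "traits.csv", "meta.csv"))
  utils::write.csv(data.frame(species = sp, abundance = sim$abundance),
                   paths[1], row.names = FALSE)
  utils::write.csv(data.frame(species = sp, trait = sim$traits),
                   paths[2], row.names = FALSE)
  utils::write.csv(data.frame(species = sp,
                              mean_abundance = sim$prior$mean_abundance),
                   paths[3], row.names = FALSE)
  invisible(paths)
}
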