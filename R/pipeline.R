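#' Run the comparative TE-dynamics pipeline on a directory of inputs
#'
#' Orchestrates the stages annotate -> date -> cluster -> ortho -> polymorph
#' -> report over a genome pair with TE annotations (and, optionally, cohort
#' deletion VCFs and a structural-variant table). Inputs follow the layout
#' written by [write_sim()] / [write_cohort()]; any input may also be given
#' explicitly. Each stage writes its TSV/JSON outputs into `out_dir` and is
#' skipped on re-runs when its output is newer than every input (delete
#' `out_dir` for a clean run). A provenance manifest (inputs, parameter
#' hash) is written alongside.
#'
#' @param input_dir Directory holding `genome_A.fa`, `genome_B.fa`,
#'   `elements_A.gff3`, `elements_B.gff3`, `domains_A.tsv`, `domains_B.tsv`,
#'   and optionally `n_regions_A.tsv`, cohort VCFs under `cohort/` and
#'   `sv.tsv`.
#' @param out_dir Output directory.
#' @param speciation_mya Species split time for the report (Mya).
#' @param dating Dating configuration ([dating_config()]).
#' @param ortho Orthology parameters ([ortho_params()]).
#' @param force Recompute all stages even if outputs are up to date.
#' @return The manifest tibble (stage, output, recomputed), invisibly; the
#'   assembled report object is written as `report.json`.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         speciation_mya = 5.88,
                         dating = dating_config(),
                         ortho = ortho_params(),
                         force = FALSE) {
  req <- c("genome_A.fa", "genome_B.fa", "elements_A.gff3", "elements_B.gff3",
           "domains_A.tsv", "domains_B.tsv")
  missing <- req[!file.exists(file.path(input_dir, req))]
  if (length(missing) > 0L) {
    abort(paste0("missing inputs in ", input_dir, ": ",
                 paste(missing, collapse = ", ")),
          class = "ltrdyn_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_paths <- file.path(input_dir, req)
  manifest <- list()
  stage <- function(name, out_file, inputs, fn) {
    out_path <- file.path(out_dir, out_file)
    fresh <- file.exists(out_path) &&
      all(file.mtime(out_path) >= file.mtime(inputs))
    if (!force && fresh) {
      manifest[[length(manifest) + 1L]] <<- tibble(stage = name, output = out_path,
                                                   recomputed = FALSE)
      return(readr::read_tsv(out_path, show_col_types = FALSE))
    }
    res <- fn()
    readr::write_tsv(res, out_path)
    manifest[[length(manifest) + 1L]] <<- tibble(stage = name, output = out_path,
                                                 recomputed = TRUE)
    res
  }

  genome_a <- as_genome(file.path(input_dir, "genome_A.fa"))
  genome_b <- as_genome(file.path(input_dir, "genome_B.fa"))
  els_a <- read_elements_gff3(file.path(input_dir, "elements_A.gff3"))
  els_b <- read_elements_gff3(file.path(input_dir, "elements_B.gff3"))
  dom_a <- readr::read_tsv(file.path(input_dir, "domains_A.tsv"), show_col_types = FALSE)
  dom_b <- readr::read_tsv(file.path(input_dir, "domains_B.tsv"), show_col_types = FALSE)

  ann_a <- stage("annotate_A", "elements_filtered_A.tsv", in_paths, function() {
    filter_elements(els_a, genome_a, dom_a) |>
      classify_superfamily(dom_a) |>
      select(-any_of(c("tsd")))
  })
  ann_b <- stage("annotate_B", "elements_filtered_B.tsv", in_paths, function() {
    filter_elements(els_b, genome_b, dom_b) |>
      classify_superfamily(dom_b) |>
      select(-any_of(c("tsd")))
  })
  kept_a <- ann_a |> filter(.data$kept)
  kept_b <- ann_b |> filter(.data$kept)

  ages_a <- stage("date_A", "ages_A.tsv", in_paths, function() {
    date_elements(kept_a, genome_a, dating)
  })
  ages_b <- stage("date_B", "ages_B.tsv", in_paths, function() {
    date_elements(kept_b, genome_b, dating)
  })

  pooled <- bind_rows(kept_a |> mutate(genome = "A"),
                      kept_b |> mutate(genome = "B"))
  clustered <- stage("cluster", "clusters.tsv", in_paths, function() {
    cluster_elements_8080(pooled, list(A = genome_a, B = genome_b))$clustered |>
      select("element_id", "genome", "cluster_id")
  })
  creport <- cluster_stats(clustered, bind_rows(ages_a, ages_b))

  idx_b <- genome_kmer_index(genome_b, k = ortho$map$k)
  idx_a <- genome_kmer_index(genome_a, k = ortho$map$k)
  calls_ab <- stage("ortho_A", "ortho_A_in_B.tsv", in_paths, function() {
    classify_orthologs(kept_a, genome_a, idx_b, ortho)
  })
  calls_ba <- stage("ortho_B", "ortho_B_in_A.tsv", in_paths, function() {
    classify_orthologs(kept_b, genome_b, idx_a, ortho)
  })

  poly <- NULL
  cohort_dir <- file.path(input_dir, "cohort")
  if (dir.exists(cohort_dir)) {
    vcfs <- list.files(cohort_dir, pattern = "\\.vcf$", full.names = TRUE)
    nreg_path <- file.path(input_dir, "n_regions_A.tsv")
    nreg <- if (file.exists(nreg_path))
      readr::read_tsv(nreg_path, show_col_types = FALSE)
    else tibble(sequence_id = character(0), start = integer(0), end = integer(0))
    calls <- map(vcfs, function(p) {
      read_deletion_vcf(p, cultivar_id = sub("\\.deletions\\.vcf$", "", basename(p)))
    }) |> list_rbind()
    poly <- stage("polymorph", "polymorphism_A.tsv", c(in_paths, vcfs), function() {
      kept <- filter_deletions(calls, nreg)
      classify_fixed_polymorphic(kept_a, kept, unique(calls$cultivar_id)) |>
        mutate(absent_in = map_chr(.data$absent_in, paste, collapse = ","),
               evidence = map_chr(.data$evidence, paste, collapse = ","))
    })
  }

  svte <- NULL
  sv_path <- file.path(input_dir, "sv.tsv")
  if (file.exists(sv_path)) {
    svte <- stage("svte", "sv_te.tsv", c(in_paths, sv_path), function() {
      read_assemblytics(sv_path) |>
        filter_sv() |>
        sv_te_associate(kept_a |> select("sequence_id", "start", "end"),
                        kept_b |> select("sequence_id", "start", "end"))
    })
  }

  report <- render_report(ages_a = ages_a, ages_b = ages_b,
                          cluster_report = creport,
                          calls_ab = calls_ab, calls_ba = calls_ba,
                          polymorphism = poly, sv_te = svte,
                          speciation_mya = speciation_mya)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  manifest <- bind_rows(manifest)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Assemble the paper-shaped summary report
#'
#' Aggregates stage outputs into one machine-readable list: per-genome age
#' histograms and recent (<= 5 Mya) fractions, cluster statistics,
#' orthology-category counts and age fractions, fixed/polymorphic counts, and
#' the SV/TE association table. The report layer adds no arithmetic beyond
#' aggregation of the stage tables.
#'
#' @param ages_a,ages_b Age tibbles per genome.
#' @param cluster_report A `cluster_report` (or `NULL`).
#' @param calls_ab,calls_ba Orthology-call tibbles (or `NULL`).
#' @param polymorphism Fixed/polymorphic tibble (or `NULL`).
#' @param sv_te SV association tibble (or `NULL`).
#' @param speciation_mya Species split (Mya).
#' @return A list of class `ltrdyn_report`.
#' @export
render_report <- function(ages_a = NULL, ages_b = NULL, cluster_report = NULL,
                          calls_ab = NULL, calls_ba = NULL,
                          polymorphism = NULL, sv_te = NULL,
                          speciation_mya = 5.88) {
  out <- list(speciation_mya = speciation_mya)
  hist_block <- function(ages) {
    if (is.null(ages)) return(NULL)
    h <- age_histogram(ages)
    list(n_dated = sum(ages$status == "dated"),
         n_saturated = sum(ages$status == "saturated"),
         n_too_short = sum(ages$status == "too_short"),
         recent_count = attr(h, "recent_count"),
         recent_fraction = attr(h, "recent_fraction"),
         bins = h)
  }
  out$ages <- list(A = hist_block(ages_a), B = hist_block(ages_b))
  if (!is.null(cluster_report)) out$clustering <- as.list(glance(cluster_report))
  cat_block <- function(calls, ages) {
    if (is.null(calls)) return(NULL)
    rep <- age_by_category(calls, ages, speciation_mya)
    list(by_category = rep$by_category,
         n_concordant = sum(calls$locus_status == "concordant"))
  }
  out$orthology <- list(A_in_B = cat_block(calls_ab, ages_a),
                        B_in_A = cat_block(calls_ba, ages_b))
  if (!is.null(polymorphism)) {
    out$polymorphism <- list(n_fixed = sum(polymorphism$status == "fixed"),
                             n_polymorphic = sum(polymorphism$status == "polymorphic"))
  }
  if (!is.null(sv_te)) out$sv_te <- sv_te_summary(sv_te)
  structure(out, class = "ltrdyn_report")
}
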