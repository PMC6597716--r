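#' Default configuration for the end-to-end analysis
#'
#' Returns the configuration list used by [run_pipeline()]. In
#' `mode = "synthetic"` every stage runs on data produced by the package's
#' own forward models; in `mode = "printed"` the kinetics/thermodynamics
#' stages use the published constants shipped with the package
#' ([ipmdh_constants()]) and the synthetic stages are skipped.
#'
#' @param mode `"synthetic"` or `"printed"`.
#' @param seed integer seed driving all randomness.
#' @param output_dir where the report bundle is written.
#' @return a named list (class `run_config`), fully serialisable to YAML.
#' @export
default_config <- function(mode = c("synthetic", "printed"), seed = 1L,
                           output_dir = tempfile("thermokin_run_")) {
  mode <- match.arg(mode)
  structure(list(
    version = as.character(utils::packageVersion("thermokin")),
    mode = mode,
    seed = as.integer(seed),
    output_dir = output_dir,
    design = list(shell_radii = c(8, 12), link_threshold = 6,
                  gap_open = 11, gap_extend = 1, offset = 0),
    kinetics = list(noise_sd = 0.01, n_conc = 8,
                    temperatures_C = c(25, 40, 70),
                    enzyme_conc = 1e-8),
    thermo = list(convention = "association", T_ref_C = 25),
    melt = list(noise_sd = 0.01, grid_from = 40, grid_to = 100,
                grid_by = 0.5),
    tradeoff = list(n_wildtype = 6)),
    class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @param config a config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(mode = cfg$mode %||% "synthetic")
  cfg <- utils::modifyList(unclass(base), cfg)
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full comparative-design / kinetics / thermodynamics pipeline
#'
#' Chains the package's stages in the order of a complete study: mutant
#' design on a structure, Michaelis-Menten fitting across temperatures,
#' reaction-coordinate energy profiles, thermal-melt analysis, and the
#' stability-activity trade-off. Writes a JSON+CSV report bundle to
#' `config$output_dir` and logs every convention and threshold used. A
#' failing stage aborts with the stage name; outputs of completed stages
#' are preserved.
#'
#' @param config a [default_config()] list, or a path to a YAML file.
#' @return the report (named list), invisibly; also written as
#'   `report.json`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(default_config("synthetic", seed = 7))
#' names(rep)
#' }
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(config), log = character(0))
  note <- function(...) {
    report$log <<- c(report$log, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      jsonlite::write_json(report, file.path(config$output_dir,
                                             "report_partial.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out_file <- function(f) file.path(config$output_dir, f)

  ## -- design stage (always synthetic: toy structure + toy alignment) ----
  stage("design", {
    seq_a <- "MKVAVLGAAGGIGQALALLLKTQLPSGSELSLYDIA"
    seq_b <- "MKVAILGAAGRIGQALALLLKTQLPAGSELSLYDVA"
    aln <- align_global(seq_a, seq_b, gap_open = config$design$gap_open,
                        gap_extend = config$design$gap_extend,
                        names = c("thermophile", "mesophile"))
    diffs <- which(aln$a != aln$b & aln$a != "-" & aln$b != "-")
    dists <- with_seed(config$seed,
                       stats::runif(length(diffs), 3, 15))
    sites <- data.frame(chain = "A", resno = aln$pos_a[diffs],
                        resname = "ALA", dist = round(dists, 2))
    pdb <- read_structure(make_toy_structure(sites))
    dmap <- compute_distance_map(pdb)
    designs_all <- list()
    for (r in config$design$shell_radii) {
      cand <- select_shell_sites(aln, dmap, radius = r,
                                 offset = config$design$offset)
      designs <- group_sites(cand, pdb,
                             link_threshold = config$design$link_threshold,
                             name_prefix = sprintf("mut%g-", r))
      designs <- apply_insertion_rule(designs, aln)
      write_design_outputs(cand, designs,
                           out_file(sprintf("candidates_%gA.tsv", r)),
                           out_file(sprintf("designs_%gA.json", r)))
      note("design: %d candidate site(s), %d construct(s) at %g A shell",
           nrow(cand), length(designs), r)
      designs_all[[as.character(r)]] <- designs
    }
    report$design <- list(
      alignment = unclass(summarize_alignment(aln)),
      n_designs = vapply(designs_all, length, integer(1)))
  })

  ## -- kinetics + thermo ------------------------------------------------
  conv <- config$thermo$convention
  T_ref <- celsius_to_kelvin(config$thermo$T_ref_C)
  if (config$mode == "synthetic") {
    stage("kinetics", {
      truths <- list(truth_preset("thermophile-like"),
                     truth_preset("mesophile-like"))
      fits <- list()
      for (tr in truths) for (tc in config$kinetics$temperatures_C) {
        km <- truth_km(tr, celsius_to_kelvin(tc))
        grid <- km * 2^seq(-2, 5, length.out = config$kinetics$n_conc)
        s <- simulate_titration(
          tr, tc, grid, config$kinetics$enzyme_conc,
          noise = noise_spec(config$kinetics$noise_sd,
                             config$seed + round(tc)))
        fits[[length(fits) + 1]] <- fit_mm(s)
      }
      tab <- do.call(rbind, lapply(fits, function(f) data.frame(
        enzyme = f$series$enzyme, temperature_C = f$series$temperature_C,
        kcat_per_s = f$kcat, kcat_se = f$kcat_se,
        Km_NAD_uM = f$Km * 1e6, Km_NAD_se = f$Km_se * 1e6,
        converged = f$converged)))
      utils::write.csv(tab, out_file("fitted_constants.csv"),
                       row.names = FALSE)
      note("kinetics: fitted %d series (noise sd %.3g)", length(fits),
           config$kinetics$noise_sd)
      report$kinetics <- tab
    })
    ktab <- report$kinetics
    ref_enz <- "thermophile-like"
  } else {
    tab <- ipmdh_constants()
    ktab <- tab[tab$table == "T2", ]
    report$kinetics <- ktab
    ref_enz <- "TtIPMDH"
    note("kinetics: using shipped printed constants (table T2)")
  }

  stage("relative tables", {
    rel <- lapply(split(ktab, ktab$temperature_C), function(d) {
      relative_table(stats::setNames(d$kcat_per_s, d$enzyme), ref_enz)
    })
    for (tc in names(rel))
      utils::write.csv(rel[[tc]], out_file(sprintf("relative_kcat_%sC.csv",
                                                   tc)),
                       row.names = FALSE)
    report$fold_changes <- fold_change_report(ktab, reference = ref_enz)
    note("relative tables: reference %s, 2 significant figures", ref_enz)
  })

  stage("thermo", {
    profiles <- lapply(split(ktab, ktab$enzyme), function(d) {
      d <- d[order(d$temperature_C), ]
      T_K <- celsius_to_kelvin(d$temperature_C)
      arr <- arrhenius_dh_act(data.frame(T_K = T_K, kcat = d$kcat_per_s),
                              T_ref = T_ref)
      vh <- vanthoff_dhm(data.frame(T_K = T_K, Km = d$Km_NAD_uM * 1e-6),
                         convention = conv)
      i <- which.min(abs(T_K - T_ref))
      assemble_profile(d$kcat_per_s[i], d$Km_NAD_uM[i] * 1e-6, arr, vh,
                       T_ref = T_ref, enzyme = d$enzyme[1],
                       convention = conv)
    })
    for (p in profiles)
      write_profile(p, out_file(sprintf("profile_%s.json",
                                        gsub("[^A-Za-z0-9]+", "_",
                                             p$enzyme))),
                    out_file(sprintf("profile_%s.tsv",
                                     gsub("[^A-Za-z0-9]+", "_",
                                          p$enzyme))))
    report$profiles <- lapply(profiles, unclass)
    if (length(profiles) >= 2)
      report$profile_comparison <-
        unclass(compare_profiles(unname(profiles)))[c("distance", "nearest")]
    note("thermo: %s convention, T_ref %.2f K", conv, T_ref)
  })

  ## -- melt + tradeoff (synthetic surfaces) ------------------------------
  stage("melt", {
    grid <- seq(config$melt$grid_from, config$melt$grid_to,
                by = config$melt$grid_by)
    wt <- truth_preset("thermophile-like")
    mut <- wt
    mut$name <- "combined-mutant-like"
    mut$Tm <- wt$Tm - 2  # best-mutant-style small stability cost
    f_wt <- fit_melt(simulate_melt(wt, grid,
                                   noise_spec(config$melt$noise_sd,
                                              config$seed + 101)))
    f_mut <- fit_melt(simulate_melt(mut, grid,
                                    noise_spec(config$melt$noise_sd,
                                               config$seed + 102)))
    dt <- delta_tm(f_mut, f_wt)
    utils::write.csv(fraction_unfolded(f_wt),
                     out_file("fraction_unfolded_wt.csv"),
                     row.names = FALSE)
    report$melt <- list(Tm_wt = f_wt$Tm, Tm_mut = f_mut$Tm,
                        delta_Tm = dt$dTm, delta_Tm_se = dt$se)
    note("melt: two-state fits, delta Tm = %.2f C", dt$dTm)
  })

  stage("tradeoff", {
    n <- config$tradeoff$n_wildtype
    pts <- with_seed(config$seed + 7, {
      Tm <- seq(50, 90, length.out = n)
      data.frame(enzyme = paste0("wt", seq_len(n)),
                 activity = 10^(4 - 0.05 * Tm + stats::rnorm(n, 0, 0.08)),
                 Tm_C = Tm, group = "wild-type")
    })
    fit <- fit_tradeoff(pts)
    escaper <- data.frame(enzyme = "escaper-mutant",
                          activity = 10^(fit$intercept + fit$slope * 86 + 1),
                          Tm_C = 86)
    devs <- deviation_from_line(fit, escaper)
    utils::write.csv(
      data.frame(enzyme = pts$enzyme, residual = fit$residuals),
      out_file("tradeoff_residuals.csv"), row.names = FALSE)
    report$tradeoff <- list(slope = fit$slope, intercept = fit$intercept,
                            r = fit$r, escaper_deviation = unname(devs))
    note("tradeoff: r = %.3f on %d wild-type points", fit$r, n)
  })

  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Validate input files against the package's expected schemas
#'
#' Diagnostic-only checks of the CSV/FASTA inputs the pipeline reads:
#' required columns, positivity, and unit plausibility (temperatures that
#' look like Kelvin, Michaelis constants that look like they were given in
#' micromolar where molar is expected).
#'
#' @param paths named character vector or list; names give the schema of
#'   each file: `"kinetic_series"`, `"melt_curve"`, `"constants"`,
#'   `"alignment_fasta"`, `"tradeoff_points"`.
#' @return data frame with columns `file`, `schema`, `level`
#'   (`"ok"`, `"warning"`, `"error"`), `message`.
#' @export
validate_inputs <- function(paths) {
  stopifnot(length(names(paths)) == length(paths))
  rows <- list()
  add <- function(file, schema, level, message) {
    rows[[length(rows) + 1]] <<- data.frame(
      file = file, schema = schema, level = level, message = message,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(paths)) {
    schema <- names(paths)[i]
    path <- paths[[i]]
    if (!file.exists(path)) {
      add(path, schema, "error", "file does not exist")
      next
    }
    res <- tryCatch(switch(
      schema,
      kinetic_series = {
        df <- utils::read.csv(path)
        need <- c("enzyme", "temperature_C", "ligand", "conc_M",
                  "enzyme_conc_M", "velocity_per_s")
        miss <- setdiff(need, names(df))
        if (length(miss))
          add(path, schema, "error",
              paste("missing column(s):", paste(miss, collapse = ", ")))
        else {
          bad <- which(df$conc_M <= 0)
          if (length(bad))
            add(path, schema, "error",
                paste("non-positive concentration in row(s):",
                      paste(utils::head(bad, 5), collapse = ", ")))
          if (any(df$temperature_C > 200))
            add(path, schema, "warning",
                "temperature above 200: Kelvin where degrees C expected?")
          if (!length(bad)) add(path, schema, "ok", "well-formed")
        }
      },
      melt_curve = {
        df <- utils::read.csv(path)
        need <- c("temperature_C", "ellipticity_mdeg")
        miss <- setdiff(need, names(df))
        if (length(miss))
          add(path, schema, "error",
              paste("missing column(s):", paste(miss, collapse = ", ")))
        else if (any(df$temperature_C > 200))
          add(path, schema, "warning",
              "temperature above 200: Kelvin where degrees C expected?")
        else add(path, schema, "ok", "well-formed")
      },
      constants = {
        df <- utils::read.csv(path)
        need <- c("enzyme", "temperature_C", "kcat_per_s", "Km_NAD_uM")
        miss <- setdiff(need, names(df))
        if (length(miss))
          add(path, schema, "error",
              paste("missing column(s):", paste(miss, collapse = ", ")))
        else {
          if (any(df$Km_NAD_uM < 1e-3, na.rm = TRUE))
            add(path, schema, "warning",
                "Km below 0.001 uM: molar value in a micromolar column?")
          add(path, schema, "ok", "well-formed")
        }
      },
      alignment_fasta = {
        ok <- tryCatch({
          read_alignment_fasta(path)
          TRUE
        }, error = function(e) {
          add(path, schema, "error", conditionMessage(e))
          FALSE
        })
        if (ok) add(path, schema, "ok", "well-formed")
      },
      tradeoff_points = {
        df <- utils::read.csv(path)
        need <- c("enzyme", "activity", "Tm_C")
        miss <- setdiff(need, names(df))
        if (length(miss))
          add(path, schema, "error",
              paste("missing column(s):", paste(miss, collapse = ", ")))
        else if (any(df$activity <= 0))
          add(path, schema, "error", "non-positive activity")
        else add(path, schema, "ok", "well-formed")
      },
      add(path, schema, "error", paste("unknown schema:", schema))),
      error = function(e) add(path, schema, "error", conditionMessage(e)))
  }
  do.call(rbind, rows)
}
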