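# Pipeline orchestration and the command-line interface.

#' Run the full assessment pipeline
#'
#' Orchestrates score -> classify -> pressure -> variance partitioning from
#' a single configuration, writing one CSV per stage plus a run log.  Every
#' stage is optional: stages run when their input file is configured.
#' Outputs are deterministic for a fixed configuration and seed (the run log
#' carries no timestamps), so reruns are byte-identical.
#'
#' @param config A list, or path to a JSON file, with entries:
#'   \describe{
#'     \item{out_dir}{output directory (required; created if absent)}
#'     \item{survey}{survey CSV -> writes `eqr_es.csv` and
#'       `dominance_profile.csv`}
#'     \item{pressures}{pressure CSV -> writes `pressures_lusi.csv`}
#'     \item{panel}{EQR panel CSV -> writes `variance_components.csv`}
#'     \item{sensitivity, reference}{optional catalogue/reference CSV paths
#'       (defaults: the shipped tables)}
#'     \item{structure}{random terms for the panel fit (default all four)}
#'     \item{cap, cap_sectors}{EQR capping flags, see [waterbody_eqr()]}
#'     \item{boundaries}{rating-scale cut points (default WFD bands)}
#'     \item{seed}{echoed into the log; reserved for stages that simulate}
#'   }
#' @return Invisibly, a list with the tables written by each stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage ", sQuote(name), " failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  catalog <- stage("catalog", if (is.null(config$sensitivity))
    default_sensitivity_catalog() else read_sensitivity_catalog(config$sensitivity))
  refs <- stage("reference", if (is.null(config$reference))
    default_reference_eqi() else read_reference_eqi(config$reference))
  scale <- stage("rating_scale", if (is.null(config$boundaries))
    rating_scale() else rating_scale(config$boundaries))
  cap <- !isFALSE(config$cap)
  out <- list()
  log_lines <- c(
    paste0("carlites version: ", as.character(utils::packageVersion("carlites"))),
    paste0("R version: ", R.version.string),
    paste0("seed: ", if (is.null(config$seed)) "none" else config$seed),
    paste0("config: ", jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                                        auto_unbox = TRUE)))

  if (!is.null(config$survey)) {
    out$eqr <- stage("score", {
      sectors <- read_survey(config$survey, refs = refs)
      res <- survey_eqr(sectors, catalog = catalog, refs = refs, cap = cap,
                        cap_sectors = isTRUE(config$cap_sectors), scale = scale)
      res$EQR <- round(res$EQR, 4)
      utils::write.csv(res, file.path(config$out_dir, "eqr_es.csv"),
                       row.names = FALSE, quote = FALSE)
      res
    })
    out$dominance <- stage("dominance", {
      sectors <- read_survey(config$survey, refs = refs)
      prof <- do.call(rbind, lapply(split(sectors, sectors$Site), function(s) {
        p <- dominance_profile(s)
        cbind(Site = s$Site[1], p)
      }))
      prof$Percent <- round(prof$Percent, 4)
      rownames(prof) <- NULL
      utils::write.csv(prof, file.path(config$out_dir, "dominance_profile.csv"),
                       row.names = FALSE, quote = FALSE)
      prof
    })
  }
  if (!is.null(config$pressures)) {
    out$lusi <- stage("pressure", {
      pr <- compute_lusi(read_pressures(config$pressures))
      utils::write.csv(pr, file.path(config$out_dir, "pressures_lusi.csv"),
                       row.names = FALSE, quote = FALSE)
      pr
    })
  }
  if (!is.null(config$panel)) {
    out$varcomp <- stage("varcomp", {
      panel <- read_panel(config$panel)
      structure <- if (is.null(config$structure))
        c("wb", "year", "surveyor", "wb_in_year") else config$structure
      fit <- fit_reml(panel, structure = structure)
      tab <- varcomp_table(fit)
      tab$Std.dev. <- round(tab$Std.dev., 6)
      tab$Variance <- round(tab$Variance, 6)
      utils::write.csv(tab, file.path(config$out_dir, "variance_components.csv"),
                       row.names = FALSE, quote = FALSE)
      log_lines <<- c(log_lines,
                      sprintf("varcomp: criterion %.6f converged %s",
                              fit$criterion, fit$converged))
      tab
    })
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(out)
}

cli_die <- function(...) {
  message("error: ", ...)
  1L
}

#' Command-line entry point
#'
#' Dispatches the subcommands `score`, `classify`, `lusi`, `varcomp`,
#' `simulate` and `run`.  An executable wrapper is installed under
#' `system.file("exec", "carlites", package = "carlites")`.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Integer exit status, invisibly (0 on success).
#' @export
carlit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: carlites <command> [options]",
    "  score    --survey F [--sl F] [--ref F] [--no-cap] [--cap-sectors] -o DIR",
    "  classify --eqr-table F [-o F]",
    "  lusi     --pressures F [-o F]",
    "  varcomp  --panel F [--structure wb,year,surveyor,wb_in_year] [-o F]",
    "  simulate survey|panel [--config F] [--seed N] -o F",
    "  run      --config F", sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  rest <- args[-1L]
  status <- tryCatch(switch(
    cmd,
    score = cli_score(rest),
    classify = cli_classify(rest),
    lusi = cli_lusi(rest),
    varcomp = cli_varcomp(rest),
    simulate = cli_simulate(rest),
    run = cli_run(rest),
    { message(usage); cli_die("unknown command ", sQuote(cmd)) }),
    error = function(e) cli_die(conditionMessage(e)))
  invisible(as.integer(status))
}

cli_opts <- function(args, option_list) {
  parser <- optparse::OptionParser(option_list = option_list,
                                   add_help_option = TRUE)
  optparse::parse_args(parser, args = args)
}

cli_score <- function(args) {
  o <- cli_opts(args, list(
    optparse::make_option("--survey", type = "character"),
    optparse::make_option("--sl", type = "character", default = NULL),
    optparse::make_option("--ref", type = "character", default = NULL),
    optparse::make_option("--no-cap", action = "store_true", default = FALSE,
                          dest = "no_cap"),
    optparse::make_option("--cap-sectors", action = "store_true",
                          default = FALSE, dest = "cap_sectors"),
    optparse::make_option(c("-o", "--out"), type = "character")))
  if (is.null(o$survey) || is.null(o$out)) {
    return(cli_die("score needs --survey and -o"))
  }
  run_pipeline(list(survey = o$survey, sensitivity = o$sl, reference = o$ref,
                    cap = !o$no_cap, cap_sectors = o$cap_sectors,
                    out_dir = o$out))
  0L
}

cli_classify <- function(args) {
  o <- cli_opts(args, list(
    optparse::make_option("--eqr-table", type = "character", dest = "eqr_table"),
    optparse::make_option(c("-o", "--out"), type = "character", default = NULL)))
  if (is.null(o$eqr_table)) return(cli_die("classify needs --eqr-table"))
  df <- utils::read.csv(o$eqr_table, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!"EQR" %in% names(df)) return(cli_die("no EQR column in ", o$eqr_table))
  df$ES <- classify_es(df$EQR)
  if (is.null(o$out)) {
    utils::write.csv(df, stdout(), row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(df, o$out, row.names = FALSE, quote = FALSE)
  }
  0L
}

cli_lusi <- function(args) {
  o <- cli_opts(args, list(
    optparse::make_option("--pressures", type = "character"),
    optparse::make_option(c("-o", "--out"), type = "character", default = NULL)))
  if (is.null(o$pressures)) return(cli_die("lusi needs --pressures"))
  pr <- compute_lusi(read_pressures(o$pressures))
  if (is.null(o$out)) {
    utils::write.csv(pr, stdout(), row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(pr, o$out, row.names = FALSE, quote = FALSE)
  }
  0L
}

cli_varcomp <- function(args) {
  o <- cli_opts(args, list(
    optparse::make_option("--panel", type = "character"),
    optparse::make_option("--structure", type = "character",
                          default = "wb,year,surveyor,wb_in_year"),
    optparse::make_option(c("-o", "--out"), type = "character", default = NULL)))
  if (is.null(o$panel)) return(cli_die("varcomp needs --panel"))
  fit <- fit_reml(read_panel(o$panel),
                  structure = strsplit(o$structure, ",")[[1L]])
  tab <- varcomp_table(fit)
  if (is.null(o$out)) {
    utils::write.csv(tab, stdout(), row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(tab, o$out, row.names = FALSE, quote = FALSE)
  }
  0L
}

cli_simulate <- function(args) {
  if (length(args) == 0L || !args[1L] %in% c("survey", "panel")) {
    return(cli_die("simulate needs a kind: survey|panel"))
  }
  kind <- args[1L]
  o <- cli_opts(args[-1L], list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option(c("-o", "--out"), type = "character")))
  if (is.null(o$out)) return(cli_die("simulate needs -o"))
  params <- if (is.null(o$config)) list()
            else jsonlite::read_json(o$config, simplifyVector = TRUE)
  params$seed <- o$seed
  df <- if (kind == "survey") do.call(simulate_survey, params)
        else do.call(simulate_eqr_panel, params)
  utils::write.csv(df, o$out, row.names = FALSE, quote = FALSE)
  0L
}

cli_run <- function(args) {
  o <- cli_opts(args, list(
    optparse::make_option("--config", type = "character")))
  if (is.null(o$config)) return(cli_die("run needs --config"))
  run_pipeline(o$config)
  0L
}
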