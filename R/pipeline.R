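# Run configuration, stage dispatch and JSON/TSV report assembly.

#' Default run configuration
#'
#' Encodes the standard analysis parameters: the PAPP-A2 propeptide offset
#' (234), the M1 (610-927), M2 (953-1160) and IGFBP5 anchor-peptide
#' (120-143, on its own chain) domain definitions, detector cutoffs, and the
#' block/KDE/EMA settings of the trajectory analysis (eight 50-ns blocks
#' over a 400-ns tail, 3 A bandwidth, closed-reference 54 A).
#'
#' @return A nested list understood by [run_pipeline()].
#' @export
default_run_config <- function() {
  list(
    entities = list(
      `PAPP-A2` = list(propeptide_offset = 234L)
    ),
    domains = list(
      M1 = list(ranges = c(610, 927), chain = "A"),
      M2 = list(ranges = c(953, 1160), chain = "A"),
      anchor = list(ranges = c(120, 143), chain = "B")
    ),
    cutoffs = list(hbond = 3.5, hydrophobic = 4.5, pipi = 6.0,
                   coordination = 2.8, water = 2.8),
    trajectory = list(n_blocks = 8, block_len = 50, tail_len = 400,
                      bandwidth = 3, ema_span = 10, frame_spacing = 0.1,
                      reference_distance = 54, reference_sd = 5.3),
    seed = 1L
  )
}

#' Read a run configuration from a YAML file
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; everything else is inherited, so a config file
#' only needs the entries it changes.
#'
#' @param path YAML file.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param config configuration list.
#' @return The config, invisibly; errors name the offending entry.
#' @export
validate_run_config <- function(config) {
  for (nm in c("entities", "domains", "cutoffs", "trajectory")) {
    if (is.null(config[[nm]])) stop("config lacks section '", nm, "'")
  }
  for (e in names(config$entities)) {
    off <- config$entities[[e]]$propeptide_offset
    if (is.null(off) || off < 0) {
      stop("entity '", e, "' needs a non-negative propeptide_offset")
    }
  }
  for (d in names(config$domains)) {
    dd <- config$domains[[d]]
    if (is.null(dd$ranges) || is.null(dd$chain)) {
      stop("domain '", d, "' needs ranges and chain")
    }
    domain_definition(d, dd$ranges, dd$chain)  # structural validation
  }
  for (co in names(config$cutoffs)) {
    if (config$cutoffs[[co]] <= 0) stop("cutoff '", co, "' must be > 0")
  }
  invisible(config)
}

.config_domain <- function(config, name) {
  dd <- config$domains[[name]]
  if (is.null(dd)) {
    stop("domain '", name, "' is not defined in the config (available: ",
         paste(names(config$domains), collapse = ", "), ")")
  }
  domain_definition(name, dd$ranges, dd$chain)
}

.stages <- c("convert-numbering", "scan-motif", "zinc-site", "network",
             "superpose", "traj-analyze", "simulate")

#' Run one analysis stage and assemble a report
#'
#' Thin driver over the package's functions: validates the configuration,
#' executes the requested stage and returns (optionally writes) a
#' self-describing JSON report carrying the inputs, parameters, seed and
#' results, so re-running from a report's parameters reproduces it
#' bit-for-bit.
#'
#' @param config configuration list (see [default_run_config()],
#'   [read_run_config()]).
#' @param stage one of `convert-numbering`, `scan-motif`, `zinc-site`,
#'   `network`, `superpose`, `traj-analyze`, `simulate`.
#' @param args stage arguments (file paths, residue indices, ...); see the
#'   individual stage functions.
#' @param out optional JSON output path.
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), stage, args = list(),
                         out = NULL) {
  if (length(stage) != 1 || !stage %in% .stages) {
    stop("unknown stage '", stage, "'; usage: one of ",
         paste(.stages, collapse = ", "))
  }
  validate_run_config(config)
  seed <- if (!is.null(args$seed)) args$seed else config$seed
  set.seed(seed)
  results <- switch(
    stage,
    "convert-numbering" = .stage_convert_numbering(config, args),
    "scan-motif" = .stage_scan_motif(config, args),
    "zinc-site" = .stage_zinc_site(config, args),
    "network" = .stage_network(config, args),
    "superpose" = .stage_superpose(config, args),
    "traj-analyze" = .stage_traj_analyze(config, args),
    "simulate" = .stage_simulate(config, args)
  )
  # large in-memory objects are recorded by class, not serialised
  params <- lapply(args, function(a) {
    if (is.atomic(a) && length(a) < 100) a else paste0("<", class(a)[1], ">")
  })
  report <- list(
    stage = stage,
    package = "pappadyn",
    version = as.character(utils::packageVersion("pappadyn")),
    seed = seed,
    parameters = params,
    config = config,
    results = results
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(report)
}

.stage_convert_numbering <- function(config, args) {
  if (is.null(args$index)) stop("convert-numbering needs args$index")
  entity <- if (is.null(args$entity)) names(config$entities)[1] else
    args$entity
  ent <- config$entities[[entity]]
  if (is.null(ent)) stop("entity '", entity, "' not in config")
  off <- ent$propeptide_offset
  from <- if (is.null(args$from)) "precursor" else args$from
  to <- if (is.null(args$to)) "mature" else args$to
  conv <- convert_numbering(args$index, numbering_scheme(from, off),
                            numbering_scheme(to, off))
  list(entity = entity, propeptide_offset = off, from = from, to = to,
       input_index = args$index, converted_index = conv)
}

.stage_scan_motif <- function(config, args) {
  seqs <- if (!is.null(args$sequence)) {
    stats::setNames(as.character(args$sequence), "input")
  } else if (!is.null(args$fasta)) {
    read_fasta(args$fasta)
  } else stop("scan-motif needs args$sequence or args$fasta")
  lapply(seqs, scan_metzincin_motif)
}

.load_structure_arg <- function(args, key = "structure") {
  obj <- args[[key]]
  if (inherits(obj, "papp_structure")) return(obj)
  if (is.character(obj)) return(read_structure(obj))
  stop("stage needs args$", key, " (path or papp_structure)")
}

.stage_zinc_site <- function(config, args) {
  s <- .load_structure_arg(args)
  chain <- args$chain
  sq <- extract_sequence(s, if (is.null(chain)) unique(s$atoms$chain)[1]
                         else chain)
  hits <- scan_metzincin_motif(sq)
  if (nrow(hits) == 0) stop("no metzincin motif found")
  site <- validate_zinc_site(s, hits[1, ],
                             coordination_cutoff = config$cutoffs$coordination,
                             water_cutoff = config$cutoffs$water,
                             chain = chain)
  met <- tryCatch(find_met_turn(s, site), error = function(e) NULL)
  list(motif = hits, validated = site$validated,
       his_residues = site$his_res,
       coordinating = site$coordinating,
       catalytic_water = site$catalytic_water,
       met_turn = met)
}

.stage_network <- function(config, args) {
  s <- .load_structure_arg(args)
  if (is.null(args$source)) stop("network needs args$source (residue index)")
  g <- build_graph(s, include_zinc = TRUE, chain = args$chain,
                   hbond_cutoff = config$cutoffs$hbond,
                   hydrophobic_cutoff = config$cutoffs$hydrophobic,
                   pipi_cutoff = config$cutoffs$pipi,
                   coordination_cutoff = config$cutoffs$coordination)
  target <- if (is.null(args$target)) "zinc" else as.character(args$target)
  p <- shortest_path(g, args$source, target)
  if (!is.null(args$edges_tsv)) write_edges_tsv(g, args$edges_tsv)
  list(n_nodes = length(g$nodes), n_edges = nrow(g$edges),
       edges = g$edges, path_found = p$found, path = p$path,
       n_hops = p$n_hops)
}

.stage_superpose <- function(config, args) {
  sa <- .load_structure_arg(args, "structure_a")
  sb <- .load_structure_arg(args, "structure_b")
  da <- .config_domain(config, args$domain_a)
  db <- .config_domain(config, args$domain_b)
  seq_a <- extract_sequence(sa, da$chain)
  seq_b <- extract_sequence(sb, db$chain)
  pairing <- residue_pairing(pair_by_alignment(seq_a, seq_b), seq_a, seq_b)
  cycles <- if (is.null(args$cycles)) 0 else args$cycles
  fit <- domain_rmsd(sa, sb, da, db, pairing, max_cycles = cycles)
  list(rmsd = fit$rmsd, rmsd_all_pairs = fit$rmsd_all,
       n_atoms = fit$n_atoms, cycles_used = fit$cycles_used,
       n_dropped = fit$n_dropped)
}

.stage_traj_analyze <- function(config, args) {
  traj <- if (inherits(args$trajectory, "papp_trajectory")) {
    args$trajectory
  } else if (is.character(args$trajectory)) {
    read_trajectory(args$trajectory,
                    frame_spacing = config$trajectory$frame_spacing)
  } else stop("traj-analyze needs args$trajectory (path or papp_trajectory)")
  da <- .config_domain(config, if (is.null(args$domain_a)) "M1" else
    args$domain_a)
  db <- .config_domain(config, if (is.null(args$domain_b)) "M2" else
    args$domain_b)
  tp <- config$trajectory
  d <- com_distance_series(traj, da, db)
  ema <- exponential_moving_average(d, span = tp$ema_span)
  bs <- block_average(d, n_blocks = tp$n_blocks, block_len = tp$block_len,
                      tail_len = tp$tail_len)
  n_tail <- round(tp$tail_len / (d$times[2] - d$times[1]))
  tail_vals <- utils::tail(d$values, n_tail)
  kde <- kde_density(tail_vals, bandwidth = tp$bandwidth)
  cls <- classify_states(d, reference_distance = tp$reference_distance,
                         reference_sd = tp$reference_sd)
  if (!is.null(args$series_tsv)) write_series_tsv(d, args$series_tsv, cls)
  if (!is.null(args$density_tsv)) {
    utils::write.table(data.frame(grid_A = kde$grid, density = kde$density),
                       args$density_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(domains = c(da$name, db$name),
       n_frames = traj$n_frames,
       block_stats = list(mean = bs$mean, sd = bs$sd,
                          block_means = bs$block_means,
                          n_blocks = bs$n_blocks, block_len = bs$block_len,
                          tail_len = bs$tail_len),
       kde_modes = kde_modes(kde),
       cutoff = cls$cutoff,
       open_fraction = cls$open_fraction,
       ema_span = tp$ema_span,
       ema_final = utils::tail(ema$values, 1))
}

.stage_simulate <- function(config, args) {
  kind <- if (is.null(args$kind)) "enzyme" else args$kind
  seed <- if (!is.null(args$seed)) args$seed else config$seed
  if (kind == "enzyme") {
    gen <- make_enzyme(enzyme_spec(seed = seed))
    if (!is.null(args$out)) write_structure(gen$structure, args$out)
    truth <- gen$truth
  } else if (kind == "dumbbell") {
    sp <- dumbbell_spec(seed = seed)
    if (!is.null(args$frames)) sp$n_frames <- as.integer(args$frames)
    gen <- make_dumbbell_trajectory(sp)
    if (!is.null(args$out)) write_structure(gen$trajectory$structure,
                                            args$out)
    truth <- list(stationary_open = gen$truth$stationary_open,
                  n_frames = gen$trajectory$n_frames,
                  mean_separation = mean(gen$truth$separations))
  } else stop("simulate kind must be 'enzyme' or 'dumbbell'")
  if (!is.null(args$truth_json)) {
    jsonlite::write_json(truth, args$truth_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  list(kind = kind, out = args$out, truth = truth)
}
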