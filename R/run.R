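# High-level run entry points used by the command-line interface: a seeded
# simulation run and a resumable training run, each archiving its full
# configuration alongside the outputs.

write_tsv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    paste(k, paste(format(cfg[[k]], digits = 17), collapse = " ")), "")
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

resolve_params <- function(params) {
  if (is.null(params)) new_parameter_set()
  else if (inherits(params, "cg_params")) params
  else read_params(params)
}

# build an extended (unfolded) starting state for a sequence by sampling
# backbone dihedrals from the Ramachandran table
unfolded_state <- function(sequence, pset, seed) {
  set.seed(seed)
  n <- length(sequence)
  ang <- sample_rama_angles(n, pset$rama$contexts$general)
  build_chain(sequence, ang[, "phi"], ang[, "psi"])
}

#' Run a seeded folding simulation
#'
#' Runs the hybrid replica-exchange sampler and writes, into `output_dir`:
#' `config.txt` (the complete run configuration including the seed),
#' `trajectory.pdb` (recorded frames of the target replica), `final.pdb`,
#' and `log.tsv` (per-frame energy, term breakdown, radius of gyration,
#' hydrogen-bond count, and RMSD to the start).  `steps = 0` writes just the
#' initial frame.  All randomness derives from `seed`.
#'
#' @param output_dir output directory (created if needed).
#' @param pdb path to a starting backbone PDB (native start), or `NULL`.
#' @param sequence residue string used with `start = "unfolded"`; defaults to
#'   the PDB's sequence.
#' @param start "native" (the PDB coordinates) or "unfolded" (extended chain
#'   with Ramachandran-sampled dihedrals).
#' @param params a `cg_params`, a parameter file path, or `NULL` for the
#'   zero-trainable default set.
#' @param steps MD steps per replica.
#' @param n_replicas,t_min,base_interval temperature ladder (see
#'   [make_ladder()]).
#' @param seed RNG seed (< 2^31).
#' @param dt,gamma,record_every,pivot_every,swap_every sampler controls.
#' @param sidechain include the side-chain belief-propagation term.
#' @return (invisibly) list with `frames`, `stats`, `swap_rate`,
#'   `pivot_rate`, `output_dir`.
#' @export
run_simulate <- function(output_dir, pdb = NULL, sequence = NULL,
                         start = c("native", "unfolded"), params = NULL,
                         steps = 1000L, n_replicas = 3L, t_min = 1,
                         base_interval = 0.1, seed = 1L, dt = 0.01,
                         gamma = 1, record_every = 50L, pivot_every = 100L,
                         swap_every = 50L, sidechain = TRUE) {
  start <- match.arg(start)
  stopifnot(seed < 2^31)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  pset <- resolve_params(params)
  if (!is.null(pdb)) {
    native <- read_backbone_pdb(pdb)
    if (is.null(sequence)) sequence <- native$seq
  } else if (is.null(sequence)) {
    cg_error("cg_config_error", "need a starting PDB or a sequence")
  }
  sequence <- check_sequence(if (length(sequence) == 1 &&
                                 nchar(sequence[1]) > 1)
    strsplit(sequence, "")[[1]] else sequence)
  set.seed(seed)
  state <- if (start == "native") {
    if (is.null(pdb))
      cg_error("cg_config_error", "native start requires a PDB")
    native
  } else {
    unfolded_state(sequence, pset, seed)
  }
  ladder <- make_ladder(n_replicas, t_min = t_min,
                        base_interval = base_interval, nres = state$nres,
                        nres_ref = 100)
  write_config(list(
    seed = seed, steps = steps, start = start,
    sequence = paste(state$seq, collapse = ""),
    n_replicas = n_replicas, t_min = t_min, base_interval = base_interval,
    temperatures = ladder$temperatures, dt = dt, gamma = gamma,
    record_every = record_every, pivot_every = pivot_every,
    swap_every = swap_every, sidechain = sidechain
  ), file.path(output_dir, "config.txt"))
  if (steps == 0L) {
    frames <- list(state)
    sim <- list(frames = frames, energies = total_energy(
      state, pset, temperature = t_min, sidechain = sidechain)$energy,
      terms = NULL, swap_rate = NA_real_, pivot_rate = NA_real_)
  } else {
    sim <- simulate_replex(state, pset, steps = steps, ladder = ladder,
                           dt = dt, gamma = gamma,
                           pivot_every = pivot_every,
                           swap_every = swap_every,
                           record_every = record_every,
                           sidechain = sidechain)
    frames <- sim$frames
  }
  write_backbone_pdb(frames, file.path(output_dir, "trajectory.pdb"))
  write_backbone_pdb(frames[[length(frames)]],
                     file.path(output_dir, "final.pdb"))
  stats <- trajectory_stats(frames, pset, reference = state,
                            exclude_termini = min(3L,
                                                  (state$nres - 1L) %/% 2L))
  stats$energy <- sim$energies
  if (!is.null(sim$terms)) stats <- cbind(stats, as.data.frame(sim$terms))
  write_tsv(stats, file.path(output_dir, "log.tsv"))
  invisible(list(frames = frames, stats = stats, swap_rate = sim$swap_rate,
                 pivot_rate = sim$pivot_rate, output_dir = output_dir))
}

#' Run (or resume) a training run
#'
#' Contrastive-divergence training over a set of native backbone PDBs.
#' Writes into `output_dir`: `manifest.tsv` (the native files), `config.txt`,
#' `history.tsv`, a checkpoint `checkpoint_<step>.params` every
#' `checkpoint_every` updates plus `final.params`, and `state.tsv` recording
#' the last completed step.  With `resume = TRUE` the run continues from the
#' latest checkpoint and — because every sampling run derives its seed from
#' the base seed and the global step counter — produces exactly the same
#' parameters as an uninterrupted run.
#'
#' @param output_dir output directory.
#' @param native_pdbs character vector of backbone PDB paths.
#' @param params starting parameters (`cg_params`, file path, or `NULL`).
#' @param n_updates total minibatch updates (the global target, including
#'   updates done before a resume).
#' @param minibatch_size,epsilon,decay_passes,steps,sidechain,seed see
#'   [train_cd()].
#' @param checkpoint_every updates between checkpoints.
#' @param resume continue from the latest checkpoint in `output_dir`.
#' @return (invisibly) the final `cd_fit`.
#' @export
run_train <- function(output_dir, native_pdbs, params = NULL,
                      n_updates = 4L, minibatch_size = 12L, epsilon = 0.1,
                      decay_passes = 2L, steps = 200L, sidechain = TRUE,
                      seed = 1L, checkpoint_every = 1L, resume = FALSE) {
  stopifnot(length(native_pdbs) >= 1, seed < 2^31)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  natives <- lapply(native_pdbs, read_backbone_pdb)
  write_tsv(data.frame(index = seq_along(native_pdbs),
                       file = native_pdbs,
                       nres = vapply(natives, function(s) s$nres, 1L)),
            file.path(output_dir, "manifest.tsv"))
  start_step <- 1L
  history <- NULL
  state_path <- file.path(output_dir, "state.tsv")
  if (resume && file.exists(state_path)) {
    st <- utils::read.table(state_path, header = TRUE, sep = "\t")
    start_step <- st$last_step + 1L
    pset <- read_params(file.path(output_dir,
                                  sprintf("checkpoint_%06d.params",
                                          st$last_step)))
    hpath <- file.path(output_dir, "history.tsv")
    if (file.exists(hpath))
      history <- utils::read.table(hpath, header = TRUE, sep = "\t")
  } else {
    pset <- resolve_params(params)
  }
  write_config(list(seed = seed, n_updates = n_updates,
                    minibatch_size = minibatch_size, epsilon = epsilon,
                    decay_passes = decay_passes, steps = steps,
                    sidechain = sidechain, n_natives = length(native_pdbs)),
               file.path(output_dir, "config.txt"))
  remaining <- n_updates - (start_step - 1L)
  fit <- NULL
  checkpoint <- function(row, p) {
    history <<- rbind(history, row)
    write_tsv(history, file.path(output_dir, "history.tsv"))
    if (row$step %% checkpoint_every == 0L || row$step == n_updates) {
      write_params(p, file.path(output_dir,
                                sprintf("checkpoint_%06d.params", row$step)))
      write_tsv(data.frame(last_step = row$step), state_path)
    }
  }
  if (remaining > 0L) {
    fit <- train_cd(natives, pset, n_updates = remaining,
                    minibatch_size = minibatch_size, epsilon = epsilon,
                    decay_passes = decay_passes, steps = steps,
                    sidechain = sidechain, seed = seed,
                    start_step = start_step, callback = checkpoint)
    pset <- fit$params
  } else {
    fit <- structure(list(params = pset, alpha = flatten_params(pset),
                          history = history,
                          config = list(n_updates = 0L,
                                        last_step = start_step - 1L,
                                        minibatch_size = minibatch_size,
                                        epsilon = epsilon,
                                        decay_passes = decay_passes,
                                        decay_factor = 0.25,
                                        n_systems = length(natives),
                                        seed = seed, steps = steps,
                                        sidechain = sidechain)),
                     class = "cd_fit")
  }
  fit$history <- history
  write_params(pset, file.path(output_dir, "final.params"))
  invisible(fit)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `exec/cgfold` script.  Subcommands:
#' `simulate` (see [run_simulate()]), `train` ([run_train()]), `analyze`
#' (trajectory statistics for a PDB trajectory) and `make-fixtures`
#' (idealized backbones written as PDB).
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
cgfold_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cgfold <simulate|train|analyze|make-fixtures> [options]",
    "  simulate      --out DIR [--pdb FILE | --sequence SEQ] [--start native|unfolded]",
    "                [--params FILE] [--steps N] [--replicas K] [--tmin T] [--seed S]",
    "  train         --out DIR --pdb FILE[,FILE...] [--params FILE] [--updates N]",
    "                [--minibatch M] [--epsilon E] [--steps N] [--seed S] [--resume]",
    "  analyze       --pdb TRAJECTORY [--ref FILE] [--out FILE]",
    "  make-fixtures --out FILE [--kind helix|strand|coil] [--nres N] [--seed S]",
    sep = "\n")
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  if (!cmd %in% c("simulate", "train", "analyze", "make-fixtures")) {
    message(usage)
    return(invisible(1L))
  }
  opt <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--")) {
      message("unexpected argument: ", rest[i]); return(invisible(1L))
    }
    if (key == "resume") {
      opt[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(rest)) {
        message("missing value for --", key); return(invisible(1L))
      }
      opt[[key]] <- rest[i + 1L]
      i <- i + 2L
    }
  }
  num <- function(k, d) if (is.null(opt[[k]])) d else as.numeric(opt[[k]])
  chr <- function(k, d = NULL) if (is.null(opt[[k]])) d else opt[[k]]
  ok <- try(switch(cmd,
    simulate = {
      run_simulate(chr("out", "cgfold_run"), pdb = chr("pdb"),
                   sequence = chr("sequence"),
                   start = chr("start", if (is.null(opt$pdb)) "unfolded"
                               else "native"),
                   params = chr("params"), steps = as.integer(num("steps", 1000)),
                   n_replicas = as.integer(num("replicas", 3)),
                   t_min = num("tmin", 1), seed = as.integer(num("seed", 1)))
      message("simulation written to ", chr("out", "cgfold_run"))
    },
    train = {
      run_train(chr("out", "cgfold_train"),
                strsplit(chr("pdb", ""), ",")[[1]],
                params = chr("params"),
                n_updates = as.integer(num("updates", 4)),
                minibatch_size = as.integer(num("minibatch", 12)),
                epsilon = num("epsilon", 0.1),
                steps = as.integer(num("steps", 200)),
                seed = as.integer(num("seed", 1)),
                resume = isTRUE(opt$resume))
      message("training written to ", chr("out", "cgfold_train"))
    },
    analyze = {
      frames <- read_backbone_pdb(chr("pdb"), model = "all")
      if (inherits(frames, "cg_backbone")) frames <- list(frames)
      ref <- if (!is.null(opt$ref)) read_backbone_pdb(chr("ref"))
      stats <- trajectory_stats(frames, reference = ref)
      out <- chr("out")
      if (is.null(out)) {
        print(stats)
      } else {
        write_tsv(stats, out)
        message("statistics written to ", out)
      }
    },
    `make-fixtures` = {
      make_backbone(chr("kind", "helix"),
                    nres = as.integer(num("nres", 10)),
                    seed = as.integer(num("seed", 1)),
                    path = chr("out", "fixture.pdb"))
      message("fixture written to ", chr("out", "fixture.pdb"))
    }), silent = TRUE)
  if (inherits(ok, "try-error")) {
    message(attr(ok, "condition")$message)
    return(invisible(1L))
  }
  invisible(0L)
}
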