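# Ground-truthed simulator. Emulates the data-generating setting the method
# targets: phased nucleosome arrays read out by native MNase-Seq, per-mark
# ChIP libraries with Poisson fragment enrichment at truly marked
# nucleosomes over a uniform background, a pure-background input library,
# and crosslinking artifacts planted as oblique or U-shaped within-
# nucleosome midpoint distributions. Every planted quantity is returned as
# ground truth so recovery is measurable.

#' Simulation configuration
#'
#' Defaults describe the reference validation condition: one 200 kb
#' chromosome tiled with 1,000 phased nucleosomes (200 bp spacing, 147 bp
#' width), 100 truly marked nucleosomes at 20-fold fragment enrichment over
#' a 0.01 fragments/bp background, and 30 planted crosslinking artifacts
#' (half oblique, half U-shaped). Gene-anchored runs of active marks and an
#' expression model are switched on by setting `n_genes > 0`.
#'
#' @param seed RNG seed; a fixed seed makes every output byte-identical.
#' @param n_chromosomes,chrom_length_bp Genome layout.
#' @param nucleosome_spacing_bp,nucleosome_width_bp Array phasing (spacing
#'   must exceed width).
#' @param fuzziness_sd_bp SD of the truncated-normal midpoint jitter around
#'   the dyad for genuine nucleosomal fragments, default 20.
#' @param mnase_depth Expected MNase fragments per nucleosome, default 20.
#' @param background_rate ChIP background, fragments per bp (0.02
#'   corresponds to a deeply sequenced ChIP library, about 60M fragments
#'   genome-wide).
#' @param input_depth_factor Input library depth relative to one ChIP
#'   library's background, default 4: one deep input is typically shared
#'   across all marks, which stabilizes the per-nucleosome background
#'   counts the fold-change gate divides by.
#' @param marks Mark names simulated (one ChIP library each).
#' @param n_marked Randomly scattered truly-marked nucleosomes (in addition
#'   to gene-anchored ones), with categories drawn over `marks`.
#' @param enrichment_fold ChIP fragment enrichment at marked nucleosomes
#'   relative to the per-nucleosome background expectation.
#' @param n_artifacts Planted artifact nucleosomes (never truly marked);
#'   alternating oblique / U-shaped, planted in every mark's library.
#' @param artifact_offset_frac Artifact midpoint offset from the dyad as a
#'   fraction of nucleosome width, default 0.4 (far beyond the shape-filter
#'   defaults by construction).
#' @param fragment_length_bp Written fragment length, default 147.
#' @param n_genes Genes with TSSs placed on nucleosome dyads; each gene
#'   plants a run of trivalent "T" nucleosomes downstream and a short run of
#'   "A" upstream.
#' @param t_down_max,a_up_max Maximum planted run lengths per gene.
#' @param expr_base Expression slope: RPKM = `expr_base` x (downstream T
#'   count) plus lognormal noise.
#' @param expr_noise_meanlog,expr_noise_sdlog Lognormal noise parameters.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 1,
                       chrom_length_bp = 200000,
                       nucleosome_spacing_bp = 200,
                       nucleosome_width_bp = 147,
                       fuzziness_sd_bp = 20,
                       mnase_depth = 20,
                       background_rate = 0.02,
                       input_depth_factor = 4,
                       marks = histone_marks(),
                       n_marked = 100,
                       enrichment_fold = 20,
                       n_artifacts = 30,
                       artifact_offset_frac = 0.4,
                       fragment_length_bp = 147,
                       n_genes = 0,
                       t_down_max = 6,
                       a_up_max = 3,
                       expr_base = 10,
                       expr_noise_meanlog = log(0.1),
                       expr_noise_sdlog = 0.5) {
  cfg <- as.list(environment())
  if (cfg$nucleosome_spacing_bp <= cfg$nucleosome_width_bp)
    stop("spacing must exceed nucleosome width")
  if (cfg$background_rate < 0 || cfg$mnase_depth < 0 ||
      cfg$enrichment_fold < 0 || cfg$fuzziness_sd_bp < 0)
    stop("rates and depths must be >= 0")
  if (cfg$n_marked < 0 || cfg$n_artifacts < 0 || cfg$n_genes < 0)
    stop("counts must be >= 0")
  if (length(cfg$marks) == 0) stop("at least one mark required")
  structure(cfg, class = "sim_config")
}

# truncated normal sampler on [lo, hi] via inverse-CDF
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  pmin(hi, pmax(lo, qnorm(u, mean, sd)))
}

.frag_df <- function(chrom, mids, cfg) {
  if (length(mids) == 0L) return(NULL)
  half <- floor(cfg$fragment_length_bp / 2)
  start <- pmax(0, round(mids) - half)
  end <- start + cfg$fragment_length_bp
  over <- end > cfg$chrom_length_bp
  end[over] <- cfg$chrom_length_bp
  start[over] <- end[over] - cfg$fragment_length_bp
  fragments(chrom, start, end)
}

# draw a multivalent category (mark subset) for a scattered marked
# nucleosome: singletons twice the weight of pairs, plus "T" when available
.draw_categories <- function(n, marks) {
  singles <- as.list(marks)
  pairs <- if (length(marks) >= 2) combn(marks, 2, simplify = FALSE) else list()
  triple <- if (all(c("H3K4me3", "H3K9ac", "H3K27ac") %in% marks))
    list(c("H3K4me3", "H3K9ac", "H3K27ac")) else list()
  pool <- c(singles, pairs, triple)
  w <- c(rep(2, length(singles)), rep(1, length(pairs)), rep(3, length(triple)))
  pool[sample.int(length(pool), n, replace = TRUE, prob = w)]
}

#' Simulate a ground-truthed dataset
#'
#' Generates the nucleosome map, MNase/input/per-mark ChIP fragment tables,
#' optional gene annotation and expression table, and the full ground truth
#' (marked ids and categories, artifact ids and shapes, per-gene planted
#' runs). With `dir` set, every piece is also written in the package's file
#' dialects (DANPOS-style map, BED fragments, BED6 genes, TSV expression and
#' truth tables) plus a JSON manifest; outputs are byte-identical across
#' runs with the same config.
#'
#' @param config [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @return List: `config`, `map`, `mnase`, `input`, `chip` (named list per
#'   mark), `genes`, `expression`, `truth` (list: `marked` with
#'   `nucleosome_id`/`category`, `per_mark` id sets, `artifacts` with
#'   `nucleosome_id`/`shape`, `genes` with planted runs), and `files`
#'   (manifest, when `dir` is given).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  width <- cfg$nucleosome_width_bp
  spacing <- cfg$nucleosome_spacing_bp
  phase <- floor((spacing - width) / 2)

  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  map_parts <- lapply(chroms, function(ch) {
    starts <- seq(phase, cfg$chrom_length_bp - width, by = spacing)
    data.frame(chrom = ch, start = starts, end = starts + width,
               stringsAsFactors = FALSE)
  })
  mp <- do.call(rbind, map_parts)
  map <- nucleosome_map(mp$chrom, mp$start, mp$end)
  n_nuc <- nrow(map)

  # --- gene-anchored truth -------------------------------------------------
  genes <- NULL
  expression <- NULL
  truth_genes <- NULL
  category <- rep(NA_character_, n_nuc)  # per-nucleosome true category
  gene_guard <- integer(0)               # ids reserved by gene windows
  if (cfg$n_genes > 0) {
    if (!all(c("H3K4me3", "H3K9ac", "H3K27ac") %in% cfg$marks))
      stop("gene-anchored simulation plants T and A runs and needs ",
           "H3K4me3, H3K9ac and H3K27ac among the simulated marks")
    guard <- ceiling(2 * 2000 / spacing) + cfg$t_down_max + cfg$a_up_max + 2
    anchors <- seq(guard, n_nuc - guard, by = 2 * guard)
    if (length(anchors) < cfg$n_genes)
      stop("genome too small for ", cfg$n_genes, " non-overlapping gene windows")
    anchors <- sort(sample(anchors, cfg$n_genes))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    t_down <- sample.int(cfg$t_down_max + 1L, cfg$n_genes, replace = TRUE) - 1L
    a_up <- sample.int(cfg$a_up_max + 1L, cfg$n_genes, replace = TRUE) - 1L
    dirn <- ifelse(strand == "+", 1L, -1L)
    for (g in seq_len(cfg$n_genes)) {
      if (t_down[g] > 0) {
        ids <- anchors[g] + dirn[g] * (0:(t_down[g] - 1L))
        category[ids] <- "T"
      }
      if (a_up[g] > 0) {
        ids <- anchors[g] - dirn[g] * (1:a_up[g])
        category[ids] <- "A"
      }
      gene_guard <- c(gene_guard, (anchors[g] - guard):(anchors[g] + guard))
    }
    genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
                        chrom = map$chrom[anchors],
                        tss = map$dyad[anchors], strand = strand,
                        stringsAsFactors = FALSE)
    truth_genes <- cbind(genes, t_down = t_down, a_up = a_up,
                         anchor_id = map$id[anchors])
    rpkm <- cfg$expr_base * t_down +
      rlnorm(cfg$n_genes, cfg$expr_noise_meanlog, cfg$expr_noise_sdlog)
    expression <- data.frame(gene_id = genes$gene_id, rpkm = rpkm,
                             stringsAsFactors = FALSE)
  }

  # --- scattered marked nucleosomes and artifacts --------------------------
  free <- setdiff(which(is.na(category)), gene_guard)
  if (cfg$n_marked + cfg$n_artifacts > length(free))
    stop("not enough unreserved nucleosomes for n_marked + n_artifacts")
  pick <- sample(free, cfg$n_marked + cfg$n_artifacts)
  scattered <- sort(pick[seq_len(cfg$n_marked)])
  art_ids <- sort(pick[cfg$n_marked + seq_len(cfg$n_artifacts)])
  if (cfg$n_marked > 0) {
    sets <- .draw_categories(cfg$n_marked, cfg$marks)
    category[scattered] <- category_label(sets)
  }
  artifacts <- data.frame(nucleosome_id = art_ids,
                          shape = rep_len(c("oblique", "u_shaped"),
                                          cfg$n_artifacts),
                          stringsAsFactors = FALSE)

  marked <- data.frame(nucleosome_id = which(!is.na(category)),
                       category = category[!is.na(category)],
                       stringsAsFactors = FALSE)
  # expand categories back to per-mark id sets
  mark_of <- function(cat) {
    key <- names(.category_aliases)[match(cat, .category_aliases)]
    strsplit(ifelse(is.na(key), cat, key), "+", fixed = TRUE)[[1]]
  }
  per_mark <- lapply(setNames(nm = cfg$marks), function(m) {
    marked$nucleosome_id[vapply(marked$category,
                                function(cat) m %in% mark_of(cat), logical(1))]
  })

  # --- fragment libraries --------------------------------------------------
  bg_library <- function(rate = cfg$background_rate) {
    parts <- lapply(chroms, function(ch) {
      n <- rpois(1, rate * cfg$chrom_length_bp)
      .frag_df(ch, floor(runif(n, 0, cfg$chrom_length_bp)), cfg)
    })
    do.call(rbind, parts)
  }
  nuc_frags <- function(ids, per_nuc_mean, midpoint_fun) {
    counts <- rpois(length(ids), per_nuc_mean)
    parts <- lapply(seq_along(ids), function(i) {
      if (counts[i] == 0L) return(NULL)
      nuc <- map[ids[i], ]
      .frag_df(nuc$chrom, midpoint_fun(counts[i], nuc), cfg)
    })
    do.call(rbind, c(parts, list(NULL)))
  }
  dyad_jitter <- function(n, nuc)
    round(.rtruncnorm(n, nuc$dyad, cfg$fuzziness_sd_bp, nuc$start, nuc$end - 1))

  mnase <- nuc_frags(seq_len(n_nuc), cfg$mnase_depth, dyad_jitter)
  input <- bg_library(cfg$background_rate * cfg$input_depth_factor)
  signal_mean <- cfg$enrichment_fold * cfg$background_rate * width
  art_off <- cfg$artifact_offset_frac * width
  art_mid <- function(shape) function(n, nuc) {
    if (shape == "oblique")
      round(.rtruncnorm(n, nuc$dyad + art_off, 5, nuc$start, nuc$end - 1))
    else {
      side <- sample(c(-1, 1), n, replace = TRUE)
      round(.rtruncnorm(n, nuc$dyad + side * art_off, 5, nuc$start, nuc$end - 1))
    }
  }
  chip <- lapply(setNames(nm = cfg$marks), function(m) {
    parts <- list(bg_library(),
                  nuc_frags(per_mark[[m]], signal_mean, dyad_jitter))
    for (shape in unique(artifacts$shape)) {
      ids <- artifacts$nucleosome_id[artifacts$shape == shape]
      parts <- c(parts, list(nuc_frags(ids, signal_mean, art_mid(shape))))
    }
    df <- do.call(rbind, parts)
    if (is.null(df)) df <- fragments(character(0), numeric(0), numeric(0))
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "library_size") <- nrow(df)
    df
  })
  attr(mnase, "library_size") <- nrow(mnase)
  attr(input, "library_size") <- nrow(input)

  truth <- list(marked = marked, per_mark = per_mark, artifacts = artifacts,
                genes = truth_genes,
                library_sizes = c(mnase = nrow(mnase), input = nrow(input),
                                  vapply(chip, nrow, integer(1))))
  out <- list(config = cfg, map = map, mnase = mnase, input = input,
              chip = chip, genes = genes, expression = expression,
              truth = truth)
  if (!is.null(dir)) out$files <- .write_sim(out, dir)
  out
}

.write_bed3 <- function(frags, path) {
  writeLines(sprintf("%s\t%d\t%d", frags$chrom, as.integer(frags$start),
                     as.integer(frags$end)), path)
}

.write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  files <- list(map = p("nucleosome_map.tsv"), mnase = p("mnase.bed"),
                input = p("input.bed"))
  # DANPOS-style dialect: 1-based inclusive with a summit column
  m <- sim$map
  writeLines(c("chr\tstart\tend\tsmt_pos",
               sprintf("%s\t%d\t%d\t%d", m$chrom, as.integer(m$start) + 1L,
                       as.integer(m$end), as.integer(m$dyad) + 1L)),
             files$map)
  .write_bed3(sim$mnase, files$mnase)
  .write_bed3(sim$input, files$input)
  for (mk in names(sim$chip)) {
    files[[paste0("chip_", mk)]] <- p("chip_", mk, ".bed")
    .write_bed3(sim$chip[[mk]], files[[paste0("chip_", mk)]])
  }
  if (!is.null(sim$genes)) {
    files$genes <- p("genes.bed")
    g <- sim$genes
    start <- ifelse(g$strand == "+", g$tss, g$tss - 999)
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", g$chrom, as.integer(start),
                       as.integer(start) + 1000L, g$gene_id, g$strand),
               files$genes)
    files$expression <- p("expression.tsv")
    writeLines(c("gene_id\trpkm",
                 sprintf("%s\t%.10g", sim$expression$gene_id,
                         sim$expression$rpkm)),
               files$expression)
  }
  files$truth_marked <- p("truth_marked.tsv")
  write.table(sim$truth$marked, files$truth_marked, sep = "\t",
              quote = FALSE, row.names = FALSE)
  files$truth_artifacts <- p("truth_artifacts.tsv")
  write.table(sim$truth$artifacts, files$truth_artifacts, sep = "\t",
              quote = FALSE, row.names = FALSE)
  files$manifest <- p("manifest.json")
  manifest <- list(seed = sim$config$seed,
                   n_nucleosomes = nrow(sim$map),
                   library_sizes = as.list(sim$truth$library_sizes),
                   files = lapply(files[names(files) != "manifest"],
                                  basename))
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  files
}
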