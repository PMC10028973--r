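# Seeded synthetic-genome simulator. Generates a toy genome with known
# ground truth: clustered constrained elements placed into CDS, promoters,
# enhancers, unannotated intergenic islands and background; scores drawn
# under phyloP semantics (neutral = signed -log10 Uniform, so BH calling has
# a correct null; constrained = -log10 of a small-p Beta draw); plus germline
# variant, CNV and somatic cohorts shaped by simple selection parameters.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: a 1 Mb contig
#' with ~3.5% of scored bases constrained, mild missingness emulating
#' unaligned bases, purifying selection depleting constrained bases among
#' common variants (`s_dep < 1`), CNV case cohorts enriched for
#' constrained-base overlap (`e_cnv`), and a somatic cohort with planted
#' driver loci mutated at `m_d` times the background rate at constrained
#' bases.
#'
#' @param contig_lengths named vector of contig lengths (bases).
#' @param constrained_fraction target fraction of the scored universe that is
#'   constrained (genome-wide analyses report ~3.5%).
#' @param element_length_mean mean constrained-element length (geometric law,
#'   minimum 2).
#' @param missing_rate fraction of bases with no score (unaligned).
#' @param genes_per_mb gene density.
#' @param class_weights constrained-base budget shares for CDS, promoter,
#'   enhancer and unannotated-island placement; the remainder is background.
#' @param island_length_range length range of unannotated constrained islands
#'   (the planted UNICORNs).
#' @param constrained_beta shape parameters of the Beta law generating
#'   p-values at constrained bases.
#' @param s_dep selection factor in (0, 1]: acceptance probability
#'   `s_dep^log10(AC)` for allele counts > 1 at constrained sites; 1 = no
#'   selection.
#' @param n_variants,an germline cohort: number of SNVs and total allele
#'   number.
#' @param cnv list: `n_case`, `n_control`, `per_sample` (mean CNVs per
#'   sample), `length_range`, `e_cnv` (case acceptance is proportional to
#'   `1 + e_cnv * constrained_fraction_of_call`), `an`, `common_avoidance`
#'   (>0 makes common deletions avoid constrained bases).
#' @param somatic list: `n_patients`, `mu_b` (per-base background mutation
#'   rate), `m_d` (rate multiplier at constrained bases of driver loci),
#'   `n_drivers`, `flank` (driver locus flank in bases), `p_pediatric`,
#'   `subgroups`.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(contig_lengths = c(chr1 = 1e6),
                       constrained_fraction = 0.035,
                       element_length_mean = 25,
                       missing_rate = 0.03,
                       genes_per_mb = 25,
                       class_weights = c(CDS = 0.25, promoter = 0.08,
                                         enhancer = 0.07, island = 0.10),
                       island_length_range = c(30, 150),
                       constrained_beta = c(0.05, 10),
                       s_dep = 0.3,
                       n_variants = 2e4,
                       an = 1e4,
                       cnv = list(),
                       somatic = list(),
                       seed = 1) {
  stopifnot(constrained_fraction > 0, constrained_fraction < 1,
            all(class_weights >= 0), sum(class_weights) <= 1,
            missing_rate >= 0, missing_rate < 1)
  cnv_def <- list(n_case = 500, n_control = 500, per_sample = 5,
                  length_range = c(300, 10000), e_cnv = 5, an = 2000,
                  common_avoidance = 0)
  cnv_def[names(cnv)] <- cnv
  som_def <- list(n_patients = 40, mu_b = 1e-6, m_d = 50, n_drivers = 1,
                  flank = 1e5, p_pediatric = 0.5,
                  subgroups = c("WNT", "SHH", "G3", "G4"))
  som_def[names(somatic)] <- somatic
  structure(list(contig_lengths = contig_lengths,
                 constrained_fraction = constrained_fraction,
                 element_length_mean = element_length_mean,
                 missing_rate = missing_rate,
                 genes_per_mb = genes_per_mb,
                 class_weights = class_weights,
                 island_length_range = island_length_range,
                 constrained_beta = constrained_beta,
                 s_dep = s_dep, n_variants = n_variants, an = an,
                 cnv = cnv_def, somatic = som_def, seed = seed),
            class = "SimConfig")
}

# place one element of length len uniformly inside `region` (interval
# matrix), avoiding occupied bases; NULL when no placement found
.place_element <- function(region, len, occ, tries = 40) {
  w <- region[, 2] - region[, 1]
  ok <- w >= len
  if (!any(ok)) return(NULL)
  reg <- region[ok, , drop = FALSE]
  w <- w[ok]
  for (t in seq_len(tries)) {
    i <- sample.int(nrow(reg), 1, prob = w - len + 1)
    s <- reg[i, 1] + sample.int(w[i] - len + 1, 1) - 1L
    if (!any(occ[(s + 1):(s + len)])) return(c(s, s + len))
  }
  NULL
}

# build one gene model: exons inside the span, CDS = transcript interval
# [u5, u5+cds_len), UTRs on either side
.sim_gene <- function(gene_id, contig, span_start, span_len, strand) {
  n_ex <- sample(3:7, 1)
  cuts <- sort(sample.int(span_len - 2L, 2L * n_ex))
  ex <- cbind(span_start + c(0L, cuts[seq(2, length(cuts), 2)]),
              c(span_start + cuts[seq(1, length(cuts), 2)],
                span_start + span_len))
  ex_len <- sum(ex[, 2] - ex[, 1])
  u5 <- min(sample(60:240, 1), ex_len %/% 4)
  u3 <- min(sample(60:240, 1), ex_len %/% 4)
  cds_len <- ((ex_len - u5 - u3) %/% 3L) * 3L
  u3 <- ex_len - u5 - cds_len
  parts <- rbind(
    data.frame(gene_id = gene_id, class = "exon",
               start = ex[, 1], end = ex[, 2]),
    .tx_to_genomic(ex, strand, u5, u5 + cds_len, "CDS", gene_id),
    .tx_to_genomic(ex, strand, 0, u5, "UTR5", gene_id),
    .tx_to_genomic(ex, strand, u5 + cds_len, ex_len, "UTR3", gene_id))
  list(gene = data.frame(gene_id = gene_id, contig = contig, strand = strand,
                         start = span_start, end = span_start + span_len),
       parts = parts)
}

# map transcript-coordinate interval [a,b) onto genomic intervals given the
# exon matrix (genomic order) and strand
.tx_to_genomic <- function(ex, strand, a, b, class, gene_id) {
  if (b <= a) return(NULL)
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  w <- ex[, 2] - ex[, 1]
  c1 <- cumsum(w)
  c0 <- c1 - w
  out <- NULL
  for (i in seq_len(nrow(ex))) {
    o0 <- max(a, c0[i]); o1 <- min(b, c1[i])
    if (o1 <= o0) next
    g <- if (strand == "+") {
      c(ex[i, 1] + o0 - c0[i], ex[i, 1] + o1 - c0[i])
    } else {
      c(ex[i, 2] - (o1 - c0[i]), ex[i, 2] - (o0 - c0[i]))
    }
    out <- rbind(out, data.frame(gene_id = gene_id, class = class,
                                 start = g[1], end = g[2]))
  }
  out
}

#' Simulate a genome: scores, annotation and ground truth
#'
#' Lays out gene models (with enhancers linked to one or two genes) on each
#' contig, places constrained elements into CDS, promoters, enhancers,
#' unannotated intergenic islands and background until the constrained-base
#' budget `round(f_c * universe)` is met exactly, then draws per-base scores:
#' neutral bases get `sign * -log10(U)` with U ~ Uniform(0,1) and a random
#' sign, constrained bases get `-log10(p)` with p ~ Beta (small-p law).
#' Unannotated islands are placed at least 1 kb away from any gene span,
#' promoter or enhancer and recorded as the planted UNICORN truth.
#'
#' @param cfg a [sim_config()].
#' @return list of class `SimGenome` with elements `track` (`ScoreTrack`),
#'   `annotation` (`GenomeAnnotation`), `truth` (`SimTruth`: constrained set,
#'   unicorn islands, driver gene ids, per-gene CDS constraint fractions),
#'   `reference` (named character vector of contig sequences) and `config`.
#' @export
simulate_genome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  cls <- cfg$contig_lengths
  total <- sum(cls)

  # --- gene layout: genes in the first ~70% of each contig, the tail left
  #     intergenic for islands and background sampling
  genes <- NULL; parts <- NULL; enh <- NULL; links <- NULL
  gi <- 0; ei <- 0
  for (ct in names(cls)) {
    L <- cls[[ct]]
    n_genes <- max(2L, round(cfg$genes_per_mb * L / 1e6))
    pos <- round(L * 0.03)
    pitch <- floor(L * 0.67 / n_genes) # genes spread over the gene zone
    for (k in seq_len(n_genes)) {
      span <- sample(6000:14000, 1)
      if (pos + span > L * 0.70) break
      gi <- gi + 1
      g <- .sim_gene(sprintf("gene%03d", gi), ct, as.integer(pos), span,
                     sample(c("+", "-"), 1))
      genes <- rbind(genes, g$gene)
      parts <- rbind(parts, g$parts)
      gap <- max(sample(4000:9000, 1), pitch - span + sample(-2000:2000, 1))
      # most genes get a linked enhancer in the downstream gap
      if (runif(1) < 0.7) {
        ei <- ei + 1
        es <- pos + span + sample(500:2000, 1)
        ew <- sample(200:800, 1)
        enh <- rbind(enh, data.frame(enhancer_id = sprintf("enh%03d", ei),
                                     contig = ct, start = es, end = es + ew))
        links <- rbind(links, data.frame(enhancer_id = sprintf("enh%03d", ei),
                                         gene_id = g$gene$gene_id))
        if (runif(1) < 0.2 && gi > 1) # some enhancers serve two genes
          links <- rbind(links,
                         data.frame(enhancer_id = sprintf("enh%03d", ei),
                                    gene_id = genes$gene_id[nrow(genes) - 1]))
      }
      pos <- pos + span + gap
    }
  }
  ann <- genome_annotation(genes, parts, cls, enhancers = enh, links = links)

  # --- constrained-base budget against the planned universe
  n_missing <- rbinom(1, total, cfg$missing_rate)
  universe <- total - n_missing
  budget <- round(cfg$constrained_fraction * universe)

  occ <- lapply(cls, function(L) logical(L))
  placed <- list()
  add <- function(ct, s, e, cls_lab) {
    occ[[ct]][(s + 1):e] <<- TRUE
    placed[[length(placed) + 1]] <<- data.frame(contig = ct, start = s,
                                                end = e, class = cls_lab)
  }
  catalog <- Reduce(cs_union, list(
    constrained_set(data.frame(contig = ann$genes$contig,
                               start = ann$genes$start, end = ann$genes$end)),
    ann_part_set(ann, "promoter"), ann_part_set(ann, "enhancer")))
  genome_cs <- constrained_set(lapply(cls, function(L)
    cbind(start = 0L, end = as.integer(L))))
  buf <- 1000L
  buffered <- constrained_set(lapply(catalog$intervals, function(m)
    cbind(pmax(m[, 1] - buf, 0L), m[, 2] + buf)))
  island_zone <- cs_setdiff(genome_cs, buffered)

  regions <- list(CDS = ann_part_set(ann, "CDS"),
                  promoter = ann_part_set(ann, "promoter"),
                  enhancer = ann_part_set(ann, "enhancer"),
                  island = island_zone)
  rlen <- function(elen) max(2L, elen)
  unicorns <- NULL
  for (class in names(cfg$class_weights)) {
    b_class <- round(budget * cfg$class_weights[[class]])
    placed_class <- 0
    reg <- regions[[class]]
    fails <- 0
    while (placed_class < b_class && fails < 200) {
      elen <- if (class == "island") {
        sample(cfg$island_length_range[1]:cfg$island_length_range[2], 1)
      } else {
        rlen(1L + stats::rgeom(1, 1 / cfg$element_length_mean))
      }
      elen <- min(elen, b_class - placed_class + 1L)
      elen <- max(elen, 2L)
      hit <- FALSE
      for (ct in sample(names(reg$intervals))) {
        m <- reg$intervals[[ct]]
        if (nrow(m) == 0) next
        pl <- .place_element(m, elen, occ[[ct]])
        if (!is.null(pl)) {
          add(ct, pl[1], pl[2], class)
          if (class == "island")
            unicorns <- rbind(unicorns, data.frame(contig = ct,
                                                   start = pl[1],
                                                   end = pl[2]))
          placed_class <- placed_class + elen
          hit <- TRUE
          break
        }
      }
      if (!hit) fails <- fails + 1
    }
  }
  # background fill to hit the budget exactly
  remaining <- budget - sum(vapply(placed, function(d)
    sum(d$end - d$start), numeric(1)))
  fails <- 0
  while (remaining > 0) {
    if (fails > 2000)
      stop("contigs too small to place the requested constrained budget")
    elen <- min(max(2L, rlen(1L + stats::rgeom(1, 1 / cfg$element_length_mean))),
                remaining)
    if (remaining - elen == 1) elen <- remaining # never strand a 1-base tail
    ct <- sample(names(cls), 1, prob = cls)
    s <- sample.int(cls[[ct]] - elen, 1) - 1L
    if (any(occ[[ct]][(s + 1):(s + elen)])) { fails <- fails + 1; next }
    add(ct, s, s + elen, "background")
    remaining <- remaining - elen
  }
  placed <- do.call(rbind, placed)
  truth_cs <- constrained_set(placed[, c("contig", "start", "end")])

  # --- scores
  scores <- lapply(setNames(names(cls), names(cls)), function(ct) {
    L <- cls[[ct]]
    u <- runif(L)
    s <- -log10(u) * sample(c(-1, 1), L, replace = TRUE)
    cons <- occ[[ct]]
    ncons <- sum(cons)
    if (ncons > 0) {
      p <- pmax(rbeta(ncons, cfg$constrained_beta[1], cfg$constrained_beta[2]),
                1e-300)
      s[cons] <- -log10(p)
    }
    s
  })
  # missing mask applied to non-constrained bases only
  if (n_missing > 0) {
    free <- lapply(names(cls), function(ct) which(!occ[[ct]]))
    nfree <- vapply(free, length, integer(1))
    tab <- pmin(drop(stats::rmultinom(1, n_missing, nfree)), nfree)
    for (i in seq_along(cls)) {
      if (tab[i] > 0)
        scores[[i]][sample(free[[i]], tab[i])] <- NA_real_
    }
  }
  track <- score_track(scores)

  # --- reference sequence
  reference <- vapply(names(cls), function(ct)
    paste(sample(c("A", "C", "G", "T"), cls[[ct]], replace = TRUE),
          collapse = ""), character(1))

  # --- truth
  drivers <- sample(ann$genes$gene_id, cfg$somatic$n_drivers)
  gene_frac <- data.frame(gene_id = ann$genes$gene_id)
  gene_frac$frac_cds_cons <- vapply(gene_frac$gene_id, function(g) {
    cds <- ann_part_set(ann, "CDS", g)
    tot <- cs_total(cds)
    if (tot == 0) return(NA_real_)
    cs_total(cs_intersect(cds, truth_cs)) / tot
  }, numeric(1))
  truth <- structure(list(
    constrained = truth_cs,
    unicorns = if (is.null(unicorns)) constrained_set() else
      constrained_set(unicorns),
    drivers = drivers,
    gene_frac = gene_frac,
    e_cnv = cfg$cnv$e_cnv,
    catalog = catalog), class = "SimTruth")

  structure(list(track = track, annotation = ann, truth = truth,
                 reference = reference, config = cfg),
            class = "SimGenome")
}

# sample n positions uniformly from the non-missing universe
.sample_universe <- function(track, n) {
  per <- lapply(track$scores, function(s) which(!is.na(s)) - 1L)
  sizes <- vapply(per, length, integer(1))
  ct <- sample(names(per), n, replace = TRUE, prob = sizes)
  tab <- table(factor(ct, levels = names(per)))
  out <- NULL
  for (i in names(per)) {
    if (tab[[i]] > 0)
      out <- rbind(out, data.frame(contig = i,
                                   pos = sample(per[[i]], tab[[i]],
                                                replace = TRUE)))
  }
  out[sample.int(nrow(out)), , drop = FALSE]
}

.other_base <- function(ref) {
  vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1), USE.NAMES = FALSE)
}

#' Simulate a germline variant cohort
#'
#' Variant positions are uniform over the scored universe; allele counts
#' follow the neutral spectrum P(AC = k) proportional to 1/k on 1..AN. At
#' constrained bases, draws with AC > 1 are accepted with probability
#' `s_dep^log10(AC)` (rejected draws are redrawn), so with `s_dep < 1`
#' constrained bases are depleted among common variants.
#'
#' @param genome a `SimGenome`.
#' @param cfg configuration (defaults to the genome's).
#' @param seed optional seed override.
#' @return data.frame with columns `contig`, `pos` (0-based), `ref`, `alt`,
#'   `AC`, `AN`, `AF`.
#' @export
simulate_variants <- function(genome, cfg = genome$config, seed = cfg$seed) {
  if (cfg$an < 2) stop("AN must be >= 2")
  set.seed(seed + 1L)
  v <- .sample_universe(genome$track, cfg$n_variants)
  v <- v[!duplicated(v), , drop = FALSE]
  ac_prob <- 1 / seq_len(cfg$an)
  cons <- logical(nrow(v))
  for (ct in unique(v$contig)) {
    i <- v$contig == ct
    cons[i] <- cs_member(genome$truth$constrained, ct, v$pos[i])
  }
  ac <- sample.int(cfg$an, nrow(v), replace = TRUE, prob = ac_prob)
  redo <- which(cons & ac > 1 &
                  runif(nrow(v)) > cfg$s_dep^log10(pmax(ac, 2)))
  while (length(redo) > 0) {
    ac[redo] <- sample.int(cfg$an, length(redo), replace = TRUE,
                           prob = ac_prob)
    acc <- ac[redo] == 1 |
      runif(length(redo)) <= cfg$s_dep^log10(pmax(ac[redo], 2))
    redo <- redo[!acc]
  }
  v$ref <- .ref_base(genome$reference, v$contig, v$pos)
  v$alt <- .other_base(v$ref)
  v$AC <- ac
  v$AN <- cfg$an
  v$AF <- v$AC / v$AN
  rownames(v) <- NULL
  v[order(v$contig, v$pos), ]
}

.ref_base <- function(reference, contig, pos) {
  out <- character(length(pos))
  for (ct in unique(contig)) {
    i <- contig == ct
    out[i] <- vapply(pos[i] + 1, function(p) substr(reference[[ct]], p, p),
                     character(1))
  }
  out
}

#' Simulate a case/control CNV cohort
#'
#' Control CNVs are placed uniformly; case CNV placements are accepted with
#' probability `(1 + e_cnv * f) / (1 + e_cnv)` where `f` is the constrained
#' fraction of the call, so `e_cnv = 0` makes arms exchangeable. Each call
#' gets an allele count from the 1/k spectrum; when `common_avoidance > 0`,
#' common (AF >= 0.005) deletions are re-placed with acceptance probability
#' `exp(-common_avoidance * constrained_count)`.
#'
#' @inheritParams simulate_variants
#' @return data.frame with columns `sample`, `label` (`case`/`control`),
#'   `contig`, `start`, `end`, `class` (`DEL`/`DUP`/`INV`), `AC`, `AN`, `AF`.
#' @export
simulate_cnv_cohort <- function(genome, cfg = genome$config,
                                seed = cfg$seed) {
  cc <- cfg$cnv
  if (cc$n_case + cc$n_control == 0) stop("cohort size 0")
  set.seed(seed + 2L)
  cls <- cfg$contig_lengths
  truth <- genome$truth$constrained
  draw_call <- function(enrich) {
    # log-uniform call lengths: the SV size spectrum is heavy on small events
    len <- round(exp(runif(1, log(cc$length_range[1]),
                           log(cc$length_range[2]))))
    repeat {
      ct <- sample(names(cls), 1, prob = cls)
      s <- sample.int(cls[[ct]] - len, 1) - 1L
      f <- cs_count(truth, ct, s, s + len) / len
      if (enrich == 0 || runif(1) <= (1 + enrich * f) / (1 + enrich))
        return(data.frame(contig = ct, start = s, end = s + len))
    }
  }
  rows <- list()
  samples <- c(sprintf("case%04d", seq_len(cc$n_case)),
               sprintf("ctrl%04d", seq_len(cc$n_control)))
  labels <- rep(c("case", "control"), c(cc$n_case, cc$n_control))
  for (i in seq_along(samples)) {
    n <- rpois(1, cc$per_sample)
    if (n == 0) next
    for (k in seq_len(n)) {
      cl <- sample(c("DEL", "DUP", "INV"), 1, prob = c(0.5, 0.3, 0.2))
      ac <- sample.int(cc$an, 1, prob = 1 / seq_len(cc$an))
      call <- draw_call(if (labels[i] == "case") cc$e_cnv else 0)
      if (cc$common_avoidance > 0 && cl == "DEL" && ac / cc$an >= 0.005) {
        repeat {
          nc <- cs_count(truth, call$contig, call$start, call$end)
          if (runif(1) <= exp(-cc$common_avoidance * nc)) break
          call <- draw_call(if (labels[i] == "case") cc$e_cnv else 0)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample = samples[i], label = labels[i], contig = call$contig,
        start = call$start, end = call$end, class = cl,
        AC = ac, AN = cc$an, AF = ac / cc$an)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a somatic mutation cohort with planted driver loci
#'
#' Each patient receives Poisson(`mu_b` x universe) background mutations
#' uniform over the scored genome. Within each planted driver gene locus
#' (introns, UTRs and `flank` bases either side of the span, CDS excluded)
#' the mutation rate at constrained bases is multiplied by `m_d`. Ages come
#' from a pediatric (< 18) / adult mixture; subgroups are sampled uniformly.
#'
#' @inheritParams simulate_variants
#' @return data.frame with columns `patient`, `age`, `subgroup`, `contig`,
#'   `pos`, `ref`, `alt`.
#' @export
simulate_somatic_cohort <- function(genome, cfg = genome$config,
                                    seed = cfg$seed) {
  sc <- cfg$somatic
  if (sc$mu_b <= 0) stop("background mutation rate must be > 0")
  stopifnot(all(genome$truth$drivers %in% genome$annotation$genes$gene_id))
  set.seed(seed + 3L)
  U <- universe_size(genome$track)

  # constrained, scored bases inside each driver locus
  driver_pos <- lapply(genome$truth$drivers, function(g) {
    loc <- gene_locus(genome$annotation, g, flank = sc$flank)
    hot <- cs_intersect(loc, genome$truth$constrained)
    do.call(rbind, lapply(names(hot$intervals), function(ct) {
      p <- cs_positions(hot, ct)
      p <- p[!is.na(genome$track$scores[[ct]][p + 1])]
      if (length(p) == 0) return(NULL)
      data.frame(contig = ct, pos = p)
    }))
  })

  ages_ped <- function(n) sample(2:17, n, replace = TRUE)
  ages_ad <- function(n) sample(18:80, n, replace = TRUE)
  rows <- list()
  for (i in seq_len(sc$n_patients)) {
    pid <- sprintf("pt%03d", i)
    ped <- runif(1) < sc$p_pediatric
    age <- if (ped) ages_ped(1) else ages_ad(1)
    grp <- sample(sc$subgroups, 1)
    n_bg <- rpois(1, sc$mu_b * U)
    muts <- if (n_bg > 0) .sample_universe(genome$track, n_bg) else NULL
    for (dp in driver_pos) {
      if (is.null(dp) || nrow(dp) == 0) next
      n_extra <- rpois(1, (sc$m_d - 1) * sc$mu_b * nrow(dp))
      if (n_extra > 0) {
        j <- sample.int(nrow(dp), n_extra, replace = TRUE)
        muts <- rbind(muts, dp[j, , drop = FALSE])
      }
    }
    if (is.null(muts) || nrow(muts) == 0) next
    muts <- muts[!duplicated(muts), , drop = FALSE] # per-patient dedup
    muts$patient <- pid
    muts$age <- age
    muts$subgroup <- grp
    rows[[length(rows) + 1]] <- muts
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(patient = character(0), age = numeric(0),
                      subgroup = character(0), contig = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0)))
  out$ref <- .ref_base(genome$reference, out$contig, out$pos)
  out$alt <- .other_base(out$ref)
  rownames(out) <- NULL
  out[, c("patient", "age", "subgroup", "contig", "pos", "ref", "alt")]
}

#' Simulate cross-species amino-acid alignment columns
#'
#' Each column is monomorphic (one residue shared by all species) with
#' probability `theta`, and otherwise i.i.d. uniform over the 20 amino
#' acids.
#'
#' @param theta per-column conservation probabilities in \[0, 1\]; length
#'   gives the number of columns.
#' @param n_species number of species (>= 2).
#' @param seed optional seed.
#' @return character matrix, columns x species.
#' @export
simulate_alignment_columns <- function(theta, n_species, seed = NULL) {
  if (n_species < 2) stop("need at least 2 species")
  stopifnot(all(theta >= 0 & theta <= 1))
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  t(vapply(theta, function(th) {
    if (runif(1) < th) rep(sample(aa, 1), n_species)
    else sample(aa, n_species, replace = TRUE)
  }, character(n_species)))
}

#' Write a simulated study to a directory
#'
#' Serializes every simulated table alongside the ground truth so tests and
#' pipelines never have to re-derive it: `scores.bedGraph`, `genes.gff3`,
#' `enhancers.bed`, `links.tsv`, `reference.fa`, `variants.vcf`, `cnv.tsv`,
#' `somatic.tsv`, `truth_constrained.tsv`, `truth_unicorns.tsv`,
#' `truth_genes.tsv`, `truth_meta.tsv`.
#'
#' @param genome a `SimGenome`.
#' @param dir output directory (created).
#' @param variants,cnv,somatic optional cohort tables to include.
#' @export
write_simulation <- function(genome, dir, variants = NULL, cnv = NULL,
                             somatic = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_score_track(genome$track, fp("scores.bedGraph"))
  write_annotation_gff3(genome$annotation, fp("genes.gff3"))
  e <- genome$annotation$enhancers
  write.table(data.frame(e$contig, e$start, e$end, e$enhancer_id),
              fp("enhancers.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(genome$annotation$links, fp("links.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(unlist(lapply(names(genome$reference), function(ct)
    c(paste0(">", ct), genome$reference[[ct]]))), fp("reference.fa"))
  tr <- genome$truth
  write.table(cs_to_df(tr$constrained), fp("truth_constrained.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cs_to_df(tr$unicorns), fp("truth_unicorns.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tr$gene_frac, fp("truth_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(key = c("e_cnv", "drivers", "seed"),
                         value = c(tr$e_cnv,
                                   paste(tr$drivers, collapse = ","),
                                   genome$config$seed)),
              fp("truth_meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(variants)) write_variants_vcf(variants, fp("variants.vcf"))
  if (!is.null(cnv)) write.table(cnv, fp("cnv.tsv"), sep = "\t",
                                 quote = FALSE, row.names = FALSE)
  if (!is.null(somatic)) write.table(somatic, fp("somatic.tsv"), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
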