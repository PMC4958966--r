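NT_BASES <- c("A", "C", "G", "T")

# evaluate code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random stop-free coding sequence
#'
#' Codons drawn uniformly from the 61 sense codons, so the frame +1
#' translation has no internal stop.
#'
#' @param n_codons Number of codons.
#' @param seed Optional seed (local to this call).
#' @return Nucleotide string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, seed = NULL) {
  sense <- names(GENETIC_CODE_1)[GENETIC_CODE_1 != "*"]
  with_seed(seed, paste(sample(sense, n_codons, replace = TRUE),
                        collapse = ""))
}

#' Mutate a nucleotide sequence
#'
#' Each site is independently substituted to a uniformly chosen different
#' base with probability `sub_prob` (no transition/transversion bias).
#' With probability `indel_prob` per site an indel is introduced
#' (insertion or deletion with equal probability, geometric length with
#' mean 2). Deterministic under a fixed seed.
#'
#' @param seq Nucleotide string.
#' @param sub_prob Per-site substitution probability in [0, 1].
#' @param indel_prob Per-site indel probability in [0, 1).
#' @param seed Optional seed (local to this call).
#' @return Mutated nucleotide string.
#' @export
mutate_seq <- function(seq, sub_prob, indel_prob = 0, seed = NULL) {
  stopifnot(sub_prob >= 0, sub_prob <= 1, indel_prob >= 0, indel_prob < 1)
  if (nchar(seq) == 0L) return("")
  with_seed(seed, {
    chars <- strsplit(seq, "")[[1]]
    n <- length(chars)
    sub_idx <- which(stats::runif(n) < sub_prob)
    for (i in sub_idx) {
      alt <- setdiff(NT_BASES, chars[i])
      chars[i] <- alt[sample.int(length(alt), 1L)]
    }
    if (indel_prob > 0) {
      pos <- which(stats::runif(n) < indel_prob)
      for (i in rev(pos)) {
        len <- stats::rgeom(1, 0.5) + 1L
        if (stats::runif(1) < 0.5) {
          ins <- sample(NT_BASES, len, replace = TRUE)
          chars <- append(chars, ins, after = i)
        } else {
          drop <- i:min(length(chars), i + len - 1L)
          chars <- chars[-drop]
        }
      }
    }
    paste(chars, collapse = "")
  })
}

#' Plant a TSD-TIR bordered element into a background sequence
#'
#' Inserts `TSD + TIR + interior + revcomp(TIR) + TSD` at `position`
#' (0-based) and records the exact planted coordinates of all five
#' segments. Optional lesions:
#'
#' * `"outer_tir_base"` — mutate the outermost base of the left TIR (the
#'   structure remains detectable with the single-first-base tolerance and
#'   is reported with `imperfect_first_base = TRUE`);
#' * `"tsd_mismatch"` — mutate one base of the right TSD copy (the
#'   structure is no longer detectable: TSD copies must match exactly).
#'
#' @param background Background nucleotide sequence.
#' @param tsd 8-nt TSD sequence (no N).
#' @param tir TIR sequence, length 8-23, must pass [composition_ok()].
#' @param interior Interior sequence, or an integer length to generate a
#'   random interior.
#' @param position 0-based insertion position within the background.
#' @param lesion `NULL`, `"outer_tir_base"`, or `"tsd_mismatch"`.
#' @param seed Optional seed (local to this call).
#' @return List with `sequence` (background with insert) and `manifest`
#'   (planted 0-based coordinates, tir_len, interior_len, lesion).
#' @export
plant_te <- function(background, tsd, tir, interior, position,
                     lesion = NULL, seed = NULL) {
  assert_nucleotide(background, "background")
  stopifnot(nchar(tsd) == 8L, !grepl("N", tsd),
            nchar(tir) >= 8L, nchar(tir) <= 23L,
            position >= 0L, position <= nchar(background))
  if (!composition_ok(tir))
    stop("TIR fails the nucleotide-composition filter; a planted structure would be undetectable by design", call. = FALSE)
  with_seed(seed, {
    if (is.numeric(interior))
      interior <- paste(sample(NT_BASES, interior, replace = TRUE),
                        collapse = "")
    t <- nchar(tir); ilen <- nchar(interior)
    left_tir <- tir
    right_tsd <- tsd
    if (!is.null(lesion)) {
      if (lesion == "outer_tir_base") {
        orig <- substr(left_tir, 1L, 1L)
        for (alt in setdiff(NT_BASES, orig)) {
          cand <- paste0(alt, substr(left_tir, 2L, t))
          if (composition_ok(cand)) { left_tir <- cand; break }
        }
      } else if (lesion == "tsd_mismatch") {
        orig <- substr(right_tsd, 1L, 1L)
        substr(right_tsd, 1L, 1L) <- setdiff(NT_BASES, orig)[1L]
      } else stop("unknown lesion kind: ", lesion)
    }
    insert <- paste0(tsd, left_tir, interior, revcomp(tir), right_tsd)
    seq <- paste0(substr(background, 1L, position),
                  insert,
                  substr(background, position + 1L, nchar(background)))
    manifest <- list(
      left_tsd_start = position,
      left_tir_start = position + 8L,
      right_tir_start = position + 8L + t + ilen,
      right_tsd_start = position + 8L + t + ilen + t,
      tsd_seq = tsd, tir_len = t, interior_len = ilen,
      lesion = if (is.null(lesion)) NA_character_ else lesion)
    list(sequence = seq, manifest = manifest)
  })
}

# Deleting `len` bases at two nearby positions can yield the same string when
# the context is periodic; such placements are alignment-ambiguous and make
# "exact position" ill-defined. These checks detect that by direct comparison.
deletion_ambiguous <- function(seq, p, len, span = 6L) {
  base <- paste0(substr(seq, 1L, p - 1L), substr(seq, p + len, nchar(seq)))
  for (s in c(-(span:1), 1:span)) {
    q <- p + s
    if (q < 1L || q + len - 1L > nchar(seq)) next
    alt <- paste0(substr(seq, 1L, q - 1L), substr(seq, q + len, nchar(seq)))
    if (alt == base) return(TRUE)
  }
  FALSE
}

insertion_ambiguous <- function(seq, p, ins, span = 6L) {
  base <- paste0(substr(seq, 1L, p), ins, substr(seq, p + 1L, nchar(seq)))
  for (s in c(-(span:1), 1:span)) {
    q <- p + s
    if (q < 0L || q > nchar(seq)) next
    alt <- paste0(substr(seq, 1L, q), ins, substr(seq, q + 1L, nchar(seq)))
    if (alt == base) return(TRUE)
  }
  FALSE
}

#' Plant disabling coding lesions into a copy of a reference CDS
#'
#' Produces a pseudogenised candidate by planting premature stop codons
#' (codon substitutions to TGA) and frameshift indels (1- or 2-nt
#' insertions or deletions) into a stop-free in-frame reference, recording
#' every planted lesion. Lesion sites are spaced at least `spacing_codons`
#' apart and kept away from both ends; indels are placed only where the
#' gap position is locally unambiguous (no equal-string alternative
#' placement within 6 nt), so the recorded positions are well-defined
#' under optimal alignment.
#'
#' @param reference Stop-free in-frame CDS (length divisible by 3).
#' @param n_stops,n_frameshifts Numbers of lesions to plant.
#' @param seed Optional seed (local to this call).
#' @param spacing_codons Minimum spacing between lesion sites in codons.
#' @return List: `candidate` (nucleotide string) and `lesions`
#'   (data.frame kind, position, indel_len) with premature-stop positions
#'   as 1-based reference codon indices and frameshift positions as
#'   1-based candidate nucleotide offsets, matching [assess_coding()]'s
#'   reporting conventions.
#' @export
plant_coding_lesions <- function(reference, n_stops, n_frameshifts,
                                 seed = NULL, spacing_codons = 12L) {
  assert_nucleotide(reference, "reference")
  n_codons <- nchar(reference) %/% 3L
  stopifnot(nchar(reference) %% 3L == 0L,
            n_stops + n_frameshifts >= 1L,
            n_codons >= 20L + spacing_codons * (n_stops + n_frameshifts))
  with_seed(seed, {
    sites <- sort(sample(seq(10L, n_codons - 10L, by = spacing_codons),
                         n_stops + n_frameshifts))
    stop_codons <- if (n_stops) sites[seq_len(n_stops)] else integer()
    fs_sites <- if (n_frameshifts)
      sites[n_stops + seq_len(n_frameshifts)] else integer()
    cand <- reference
    for (cd in stop_codons) {
      s0 <- 3L * (cd - 1L) + 1L
      substr(cand, s0, s0 + 2L) <- "TGA"
    }
    n_fs <- length(fs_sites)
    fs_pos <- 3L * (fs_sites - 1L) + 2L     # mid-codon of each site
    fs_len <- if (n_fs) sample(1:2, n_fs, replace = TRUE) else integer()
    fs_op <- if (n_fs) sample(c("del", "ins"), n_fs, replace = TRUE)
             else character()
    # nudge ambiguous placements (and, for insertions, retry the inserted
    # string) until the gap position is locally unique
    fs_ins <- rep(NA_character_, n_fs)
    offsets <- c(0L, as.vector(rbind(1:10, -(1:10))))
    for (i in seq_len(n_fs)) {
      placed <- FALSE
      for (off in offsets) {
        p0 <- fs_pos[i] + off
        if (fs_op[i] == "del") {
          if (!deletion_ambiguous(cand, p0, fs_len[i])) {
            fs_pos[i] <- p0; placed <- TRUE; break
          }
        } else {
          cands <- apply(expand.grid(rep(list(NT_BASES), fs_len[i])), 1L,
                         paste, collapse = "")
          for (ins_str in sample(cands)) {
            if (!insertion_ambiguous(cand, p0, ins_str)) {
              fs_pos[i] <- p0; fs_ins[i] <- ins_str; placed <- TRUE; break
            }
          }
          if (placed) break
        }
      }
      if (!placed) stop("no unambiguous indel site found near codon ",
                        fs_sites[i])
    }
    for (i in rev(seq_len(n_fs))) {
      p0 <- fs_pos[i]
      if (fs_op[i] == "del") {
        cand <- paste0(substr(cand, 1L, p0 - 1L),
                       substr(cand, p0 + fs_len[i], nchar(cand)))
      } else {
        cand <- paste0(substr(cand, 1L, p0), fs_ins[i],
                       substr(cand, p0 + 1L, nchar(cand)))
      }
    }
    lesions <- data.frame(kind = character(), position = integer(),
                          indel_len = integer(), stringsAsFactors = FALSE)
    for (cd in stop_codons)
      lesions <- rbind(lesions, data.frame(
        kind = "premature_stop", position = cd, indel_len = NA_integer_,
        stringsAsFactors = FALSE))
    shift <- 0L
    for (i in seq_len(n_fs)) {
      pos <- if (fs_op[i] == "del") fs_pos[i] + shift
             else fs_pos[i] + shift + 1L
      lesions <- rbind(lesions, data.frame(
        kind = "frameshift_indel", position = pos, indel_len = fs_len[i],
        stringsAsFactors = FALSE))
      shift <- shift + if (fs_op[i] == "del") -fs_len[i] else fs_len[i]
    }
    list(candidate = cand, lesions = lesions)
  })
}

#' Default simulation configuration for the screen
#'
#' @param seed Master seed.
#' @param n_native,n_foreign,n_contaminant Transcript counts.
#' @param len_range_codons Gene length range in codons.
#' @param sub_prob_ingroup Divergence between a native transcript and its
#'   closest ingroup homolog (recent shared ancestry).
#' @param sub_prob_donor Divergence across the ingroup/outgroup split
#'   (native vs outgroup homolog, foreign vs ingroup homolog).
#' @param sub_prob_foreign_vs_donor Divergence between a planted foreign
#'   transcript and its donor-taxon homolog (recent transfer).
#' @param indel_prob Per-site indel probability for transcripts.
#' @param stage_labels,pre_attachment Developmental stage labels and the
#'   pre-attachment subset.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_native = 20L, n_foreign = 5L,
                       n_contaminant = 3L,
                       len_range_codons = c(150L, 400L),
                       sub_prob_ingroup = 0.05,
                       sub_prob_donor = 0.35,
                       sub_prob_foreign_vs_donor = 0.05,
                       indel_prob = 0,
                       stage_labels = c("0G", "2G", "3G", "4.1G", "4.2G",
                                        "5.1G", "5.2G", "6.1G", "6.2G"),
                       pre_attachment = c("0G", "2G")) {
  stopifnot(n_native >= 0, n_foreign >= 0, n_contaminant >= 0,
            all(pre_attachment %in% stage_labels))
  structure(list(seed = seed, n_native = n_native, n_foreign = n_foreign,
                 n_contaminant = n_contaminant,
                 len_range_codons = len_range_codons,
                 sub_prob_ingroup = sub_prob_ingroup,
                 sub_prob_donor = sub_prob_donor,
                 sub_prob_foreign_vs_donor = sub_prob_foreign_vs_donor,
                 indel_prob = indel_prob,
                 stage_labels = stage_labels,
                 pre_attachment = pre_attachment),
            class = "sim_config")
}

# mutate, retrying deterministically until the product keeps an ORF longer
# than min_aa (mutations occasionally create stop codons)
mutate_keep_orf <- function(seq, sub_prob, indel_prob, seed, min_aa = 100L) {
  for (attempt in 0:99) {
    m <- mutate_seq(seq, sub_prob, indel_prob, seed = seed + attempt)
    if (nrow(find_orfs(m, min_aa = min_aa)) > 0L) return(m)
  }
  stop("could not generate a mutated sequence retaining a long ORF")
}

orf_peptides <- function(seq, id, min_aa = 30L) {
  orfs <- find_orfs(seq, id = id, min_aa = min_aa)
  if (nrow(orfs) == 0L) return(character())
  orfs$peptide[order(-orfs$length_aa)]
}

#' Generate a full synthetic screening dataset with ground truth
#'
#' Emulates the statistical structure the foreign-gene screen assumes:
#' native transcripts descend from ancestors shared (recently) with the
#' closest ingroup relative; foreign transcripts descend from donor-taxon
#' (outgroup) genes; host-contaminant transcripts are expressed only in
#' post-attachment stages. Protein- and nucleotide-level hit tables are
#' computed with the built-in aligner against the simulated ingroup/donor
#' reference sets, so no external search tool is required.
#'
#' @param config A [sim_config()].
#' @return List: transcripts (named character), stage_table (data.frame),
#'   protein_hits, nt_hits (hit data.frames), taxon_map (named character),
#'   partition ([taxonomy_partition()]), manifest (data.frame
#'   transcript_id, class), config.
#' @export
make_screen_dataset <- function(config = sim_config()) {
  cfg <- config
  ids_native <- if (cfg$n_native > 0)
    sprintf("native_%03d", seq_len(cfg$n_native)) else character()
  ids_foreign <- if (cfg$n_foreign > 0)
    sprintf("foreign_%03d", seq_len(cfg$n_foreign)) else character()
  ids_contam <- if (cfg$n_contaminant > 0)
    sprintf("contam_%03d", seq_len(cfg$n_contaminant)) else character()
  classes <- c(rep("native", cfg$n_native), rep("foreign", cfg$n_foreign),
               rep("contaminant", cfg$n_contaminant))
  ids <- c(ids_native, ids_foreign, ids_contam)

  partition <- taxonomy_partition(
    ingroup = "Mimulus_guttatus",
    outgroup = c("Sisymbrium_irio", "Arabidopsis_thaliana"),
    self = "Phelipanche_aegyptiaca",
    relative = "Mimulus_guttatus")
  taxon_map <- c(MIG = "Mimulus_guttatus", SIR = "Sisymbrium_irio",
                 ATH = "Arabidopsis_thaliana")

  if (length(ids) == 0L)
    return(list(transcripts = character(), stage_table = data.frame(
      transcript_id = character(), stage = character(),
      abundance = numeric(), stringsAsFactors = FALSE),
      protein_hits = empty_hits(), nt_hits = empty_hits(),
      taxon_map = taxon_map, partition = partition,
      manifest = data.frame(transcript_id = character(),
                            class = character(), stringsAsFactors = FALSE),
      config = cfg))

  nt_scheme <- scoring_scheme("nucleotide")
  aa_scheme <- scoring_scheme("protein")
  transcripts <- character()
  refs_nt <- character()   # named: subject ids with taxon prefixes
  pairs <- list()          # transcript id -> its reference subject ids

  k <- 0L
  for (idx in seq_along(ids)) {
    id <- ids[idx]; cls <- classes[idx]
    k <- k + 1L
    base_seed <- cfg$seed * 10000L + k * 100L
    n_codons <- with_seed(base_seed,
      sample(cfg$len_range_codons[1]:cfg$len_range_codons[2], 1L))
    ancestor <- random_cds(n_codons, seed = base_seed + 1L)
    if (cls == "native") {
      transcript <- mutate_keep_orf(ancestor, cfg$sub_prob_ingroup,
                                    cfg$indel_prob, base_seed + 2L)
      near <- mutate_seq(ancestor, cfg$sub_prob_ingroup, seed = base_seed + 3L)
      far <- mutate_seq(ancestor, cfg$sub_prob_donor, seed = base_seed + 4L)
      subj <- c(paste0("MIG|", id), paste0("SIR|", id))
      refs_nt[subj] <- c(near, far)
    } else if (cls == "foreign") {
      transcript <- mutate_keep_orf(ancestor, cfg$sub_prob_foreign_vs_donor,
                                    cfg$indel_prob, base_seed + 2L)
      donor <- ancestor                                    # donor gene itself
      donor2 <- mutate_seq(ancestor, 3 * cfg$sub_prob_foreign_vs_donor,
                           seed = base_seed + 3L)          # other outgroup
      far <- mutate_seq(ancestor, cfg$sub_prob_donor, seed = base_seed + 4L)
      subj <- c(paste0("SIR|", id), paste0("ATH|", id), paste0("MIG|", id))
      refs_nt[subj] <- c(donor, donor2, far)
    } else {
      transcript <- mutate_keep_orf(ancestor, cfg$sub_prob_foreign_vs_donor,
                                    cfg$indel_prob, base_seed + 2L)
      near <- mutate_seq(ancestor, cfg$sub_prob_foreign_vs_donor,
                         seed = base_seed + 3L)            # host gene
      far <- mutate_seq(ancestor, cfg$sub_prob_donor, seed = base_seed + 4L)
      subj <- c(paste0("ATH|", id), paste0("MIG|", id))
      refs_nt[subj] <- c(near, far)
    }
    transcripts[id] <- transcript
    pairs[[id]] <- subj
  }

  # hit tables via the built-in aligner (each transcript vs its homolog set);
  # protein evidence is the best alignment over all long ORF translations,
  # mirroring a translated search of the whole transcript
  prot_rows <- list(); nt_rows <- list()
  for (id in ids) {
    qpeps <- orf_peptides(transcripts[[id]], id)
    for (subj in pairs[[id]]) {
      h_nt <- local_align(transcripts[[id]], refs_nt[[subj]], nt_scheme,
                          query_id = id, subject_id = subj)
      if (!is.null(h_nt)) nt_rows[[length(nt_rows) + 1L]] <- h_nt
      spep <- translate_frame(refs_nt[[subj]], 1L)
      best_aa <- NULL
      for (qpep in qpeps) {
        h_aa <- local_align(qpep, spep, aa_scheme,
                            query_id = id, subject_id = subj)
        if (!is.null(h_aa) &&
            (is.null(best_aa) || h_aa$bitscore > best_aa$bitscore))
          best_aa <- h_aa
      }
      if (!is.null(best_aa)) prot_rows[[length(prot_rows) + 1L]] <- best_aa
    }
  }
  protein_hits <- if (length(prot_rows)) do.call(rbind, prot_rows) else empty_hits()
  nt_hits <- if (length(nt_rows)) do.call(rbind, nt_rows) else empty_hits()
  if (nrow(protein_hits))
    protein_hits$subject_taxon <- map_taxon(protein_hits$subject_id, taxon_map)
  if (nrow(nt_hits))
    nt_hits$subject_taxon <- map_taxon(nt_hits$subject_id, taxon_map)

  # stage-expression table: contaminants silent before host attachment
  post <- setdiff(cfg$stage_labels, cfg$pre_attachment)
  stage_rows <- list()
  for (idx in seq_along(ids)) {
    id <- ids[idx]
    ab <- with_seed(cfg$seed * 10000L + idx,
                    stats::runif(length(cfg$stage_labels), 1, 50))
    if (classes[idx] == "contaminant")
      ab[cfg$stage_labels %in% cfg$pre_attachment] <- 0
    stage_rows[[idx]] <- data.frame(
      transcript_id = id, stage = cfg$stage_labels, abundance = ab,
      stringsAsFactors = FALSE)
  }
  stage_table <- do.call(rbind, stage_rows)
  rownames(stage_table) <- NULL

  list(transcripts = transcripts, stage_table = stage_table,
       protein_hits = protein_hits, nt_hits = nt_hits,
       taxon_map = taxon_map, partition = partition,
       references = refs_nt,
       manifest = data.frame(transcript_id = ids, class = classes,
                             stringsAsFactors = FALSE),
       config = cfg)
}

#' Write a screening dataset to disk in the pipeline's input formats
#'
#' Writes transcripts.fasta, stage_table.tsv, protein_hits.tsv,
#' nt_hits.tsv (BLAST tabular 6), taxon_map.tsv and manifest.json (which
#' embeds the configuration echo and its hash).
#'
#' @param dataset Result of [make_screen_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_screen_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$transcripts, file.path(dir, "transcripts.fasta"))
  write.table(dataset$stage_table, file.path(dir, "stage_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_hit_table(dataset$protein_hits, file.path(dir, "protein_hits.tsv"))
  write_hit_table(dataset$nt_hits, file.path(dir, "nt_hits.tsv"))
  write.table(data.frame(prefix = names(dataset$taxon_map),
                         taxon = unname(dataset$taxon_map)),
              file.path(dir, "taxon_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cfg <- unclass(dataset$config)
  jsonlite::write_json(
    list(config = cfg,
         config_hash = config_hash(cfg),
         manifest = dataset$manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

config_hash <- function(cfg) {
  # order-stable hash of the configuration echo
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA)
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(as.character(s))) %% 97L)) %% 1000000007
}

#' Apply loss/inversion edits to a reference gene-order table
#'
#' @param reference Reference [gene_order_table()].
#' @param edits Named list, one entry per species:
#'   `list(lose = <anchor labels>, flip = <labels>, reverse = <logical>)`.
#' @return List with `tables` (one edited [gene_order_table()] per
#'   species) and `manifest` (the applied edits).
#' @export
make_synteny_tables <- function(reference, edits) {
  tables <- list()
  for (sp in names(edits)) {
    e <- edits[[sp]]
    tab <- reference
    tab$species <- sp
    known <- tab$anchor[!is.na(tab$anchor)]
    for (lab in c(e$lose, e$flip))
      if (!lab %in% known)
        stop(sprintf("edit for %s names absent anchor '%s'", sp, lab),
             call. = FALSE)
    if (length(e$lose))
      tab <- tab[!(tab$anchor %in% e$lose) | is.na(tab$anchor), , drop = FALSE]
    if (length(e$flip)) {
      sel <- !is.na(tab$anchor) & tab$anchor %in% e$flip
      tab$strand[sel] <- flip_strand(tab$strand[sel])
    }
    if (isTRUE(e$reverse)) {
      tab <- tab[rev(seq_len(nrow(tab))), , drop = FALSE]
      tab$strand <- flip_strand(tab$strand)
    }
    tab$position <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    class(tab) <- c("gene_order_table", "data.frame")
    tables[[sp]] <- tab
  }
  list(tables = tables, manifest = edits)
}

#' Reference gene-order arrangement used by the synthetic synteny fixtures
#'
#' Six anchors (a, b upstream; 1-4 downstream) around a tandem of three
#' transposase genes (BO1, BO2a, BO2b), with interspersed unlabelled loci,
#' all on the plus strand.
#'
#' @param species Species name for the reference row set.
#' @return A [gene_order_table()].
#' @export
reference_gene_order <- function(species = "reference") {
  gene_order_table(
    species,
    locus_id = sprintf("L%02d", 1:12),
    anchor = c(NA, "a", "b", "BO1", "BO2a", "BO2b", NA, "1", "2", "3", "4", NA),
    strand = "+")
}
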