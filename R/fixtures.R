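# Deterministic synthetic-abstract generator with gold annotations.
#
# Each synthetic abstract instantiates one sentence-construction template
# family with slot fillers drawn from the bundled lexicons, surrounded by
# trigger-free filler sentences, and carries the complete gold record the
# pipeline is expected to recover. Type C and distractor families carry empty
# gold. A fraction of the comparison/level families state only a generic
# sample ("cancer tissues") in the relation sentence and put the disease in
# the title or in a patient-count methods sentence, exercising disease
# inference from context.

.FIX_GENES <- c(EGFR = "1956", PTEN = "5728", GALNT2 = "2590",
                TRIM32 = "22954", IGF1R = "3480", STAT3 = "6774",
                GPC5 = "2262", NAMPT = "10135", FUT8 = "2530",
                MGAT5 = "4249")
.FIX_MIRNAS <- c("miR-21" = "mir-21", "miR-155" = "mir-155",
                 "miR-210" = "mir-210", "miR-34a" = "mir-34a",
                 "miR-126" = "mir-126", "miR-375" = "mir-375",
                 "let-7a" = "let-7a")
.FIX_DISEASES <- c("gastric cancer" = "DOID:10534",
                   "lung cancer" = "DOID:1324",
                   "breast cancer" = "DOID:1612",
                   "colorectal cancer" = "DOID:9256",
                   "pancreatic cancer" = "DOID:1793",
                   "ovarian cancer" = "DOID:2394",
                   "prostate cancer" = "DOID:10283",
                   "hepatocellular carcinoma" = "DOID:684",
                   "melanoma" = "DOID:1909",
                   "bladder cancer" = "DOID:11054")
.FIX_SAMPLES <- c("tissues", "samples", "specimens")
.FIX_CTRL <- c("normal", "adjacent", "healthy")
.FIX_FILLERS <- c(
  "Reliable biomarkers are needed for early diagnosis.",
  "The prognostic value of this marker remains unclear.",
  "Further validation in larger cohorts is warranted.",
  "These findings may have therapeutic implications.",
  "The underlying regulatory mechanisms remain poorly understood.",
  "Tissue specimens were processed according to standard protocols.")

.DEFAULT_MIX <- c(P1 = 0.14, P2 = 0.12, P3 = 0.10, P4 = 0.08, P5 = 0.08,
                  Q1 = 0.16, Q2 = 0.12, Q3 = 0.08, TypeC = 0.06,
                  distractor = 0.06)

.pick <- function(x, n = 1L) x[sample.int(length(x), n)]

# instantiate one template family; returns title, body sentences and gold
.fix_instance <- function(family) {
  gene_i <- .pick(seq_along(.FIX_GENES))
  use_mirna <- runif(1) < 0.4 && !family %in% c("P5")
  ent <- if (use_mirna) .pick(names(.FIX_MIRNAS)) else names(.FIX_GENES)[gene_i]
  ent_norm <- if (use_mirna) .FIX_MIRNAS[[ent]] else unname(.FIX_GENES[gene_i])
  ent_kind <- if (use_mirna) "mirna" else "gene"
  dis_i <- .pick(seq_along(.FIX_DISEASES))
  disease <- names(.FIX_DISEASES)[dis_i]
  doid <- unname(.FIX_DISEASES[dis_i])
  sample <- .pick(.FIX_SAMPLES)
  ctrl <- .pick(.FIX_CTRL)
  high <- runif(1) < 0.5
  ctx <- family %in% c("P1", "P2", "Q1") && runif(1) < 0.25
  ctx_title <- ctx && runif(1) < 0.5
  not_control <- family == "P1" && !ctx && runif(1) < 0.2
  dis2 <- names(.FIX_DISEASES)[.pick(setdiff(seq_along(.FIX_DISEASES), dis_i))]

  ce1 <- if (ctx) "cancer tissues" else paste(disease, sample)
  ce2 <- if (not_control) paste(dis2, sample) else paste(ctrl, sample)
  frame <- NA_character_; rel_type <- "A"
  sent <- switch(family,
    P1 = {
      frame <- if (not_control) "Not_Control" else "Control"
      sprintf("%s expression was significantly %s in %s than in %s.",
              ent, if (high) "higher" else "lower", ce1, ce2)
    },
    P2 = {
      frame <- "Control"
      sprintf("%s levels were %s in %s compared with %s.",
              ent, if (high) "increased" else "decreased", ce1, ce2)
    },
    P3 = {
      frame <- "Control"
      sprintf("%s %s expression was %s in %s compared to %s %s.",
              if (high) "Higher" else "Lower", ent, .pick(c("observed", "found", "detected")),
              paste(disease, sample), ctrl, sample)
    },
    P4 = {
      frame <- "Control"
      sprintf("In comparison to %s %s, %s expression was significantly %s in %s %s.",
              ctrl, sample, ent, if (high) "elevated" else "reduced",
              disease, sample)
    },
    P5 = {
      frame <- "Control"
      sprintf("Compared to controls, patients with %s presented a %s expression level of %s mRNA.",
              disease, if (high) "higher" else "lower", ent)
    },
    Q1 = {
      rel_type <- "B"
      implicit <- runif(1) < 0.6
      frame <- if (implicit) "Control_Implicit" else "none"
      el <- if (ctx) "cancer tissues" else paste(disease, sample)
      if (implicit)
        sprintf("%s was frequently %s in %s.", ent,
                if (high) .pick(c("overexpressed", "upregulated"))
                else .pick(c("underexpressed", "downregulated")), el)
      else
        sprintf("%s expression was %s in %s.", ent,
                if (high) "high" else "low", el)
    },
    Q2 = {
      rel_type <- "B"
      implicit <- runif(1) < 0.5
      frame <- if (implicit) "Control_Implicit" else "none"
      sprintf("%s %s expression levels were %s in %s %s.",
              if (implicit) (if (high) "Higher" else "Lower")
              else (if (high) "High" else "Low"),
              ent, .pick(c("detected", "observed", "found")), disease, sample)
    },
    Q3 = {
      rel_type <- "B"
      frame <- "none"
      sprintf("We found %s expression levels of %s in %s %s.",
              if (high) "high" else "low", ent, disease, sample)
    },
    TypeC = sprintf("Overexpression of %s enhanced %s cell growth and invasion.",
                    ent, disease),
    distractor = "The patient cohort was followed for five years.")

  title <- if (ctx_title) {
    sprintf("Clinical significance of %s in %s.", ent, disease)
  } else if (ctx) {
    "A prospective biomarker study."
  } else {
    sprintf("Clinical significance of %s in %s.", ent, disease)
  }
  body <- c(.pick(.FIX_FILLERS))
  if (ctx && !ctx_title) {
    body <- c(body, sprintf(
      "A total of %d patients with %s were enrolled in this study.",
      sample.int(260, 1) + 39L, disease))
  }
  body <- c(body, sent)
  n_extra <- sample.int(2L, 1L) - 1L
  if (n_extra > 0) body <- c(body, .pick(setdiff(.FIX_FILLERS, body), n_extra))
  gold <- NULL
  if (!family %in% c("TypeC", "distractor")) {
    gold <- tibble::tibble(
      family = family, relation_type = rel_type,
      entity_kind = ent_kind, entity_norm = ent_norm,
      level = if (high) "High" else "Low",
      doid = doid, frame_of_reference = frame,
      disease_source = if (ctx_title) "title" else if (ctx) "analyzed" else "sentence")
  }
  list(title = title, body = body, gold = gold)
}

#' Generate synthetic abstracts with gold annotations
#'
#' Deterministic in `seed`: the same seed and arguments reproduce the same
#' abstracts and gold records. The default family mix covers all supported
#' construction families plus Type C and trigger-free distractor abstracts.
#'
#' @param n Number of abstracts (>= 0).
#' @param seed Integer seed.
#' @param mix Named probability vector over template families (normalized
#'   internally).
#' @return List with `abstracts` (list of `exprel_abstract`) and `gold`
#'   (tibble with `pmid`, `family`, `relation_type`, `entity_kind`,
#'   `entity_norm`, `level`, `doid`, `frame_of_reference`,
#'   `disease_source`).
#' @export
generate_fixtures <- function(n, seed = 1L, mix = NULL) {
  stopifnot(n >= 0)
  if (is.null(mix)) mix <- .DEFAULT_MIX
  stopifnot(all(names(mix) %in% names(.DEFAULT_MIX)), all(mix >= 0), sum(mix) > 0)
  mix <- mix / sum(mix)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  abstracts <- vector("list", n)
  gold <- list()
  if (n > 0) {
    fams <- sample(names(mix), n, replace = TRUE, prob = mix)
    for (i in seq_len(n)) {
      inst <- .fix_instance(fams[i])
      pmid <- sprintf("9%07d", i)
      abstracts[[i]] <- abstract(pmid, inst$title,
                                 paste(inst$body, collapse = " "))
      if (!is.null(inst$gold)) {
        inst$gold$pmid <- pmid
        gold[[length(gold) + 1L]] <- inst$gold
      }
    }
  }
  gold <- if (length(gold)) do.call(rbind, gold) else
    tibble::tibble(family = character(0), relation_type = character(0),
                   entity_kind = character(0), entity_norm = character(0),
                   level = character(0), doid = character(0),
                   frame_of_reference = character(0),
                   disease_source = character(0), pmid = character(0))
  gold <- gold[, c("pmid", setdiff(names(gold), "pmid"))]
  list(abstracts = abstracts, gold = gold)
}
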