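# Synthetic fixtures: worked concept descriptions with gold segmentations,
# ground-truth HMMs, a tagged-corpus sampler and an evaluation-set generator
# emulating SNOMED CT style concept descriptions. Everything is seeded and
# deterministic, so training, decoding and evaluation are testable without
# licensed corpora (SNOMED CT, Penn Treebank, MedPost).

#' Worked example concept descriptions with gold segmentations
#'
#' Seven short clinical concept descriptions covering the documented
#' ambiguity sources: parenthesized semantic tags, standalone dashes and
#' hyphenated words, fused quantity-unit tokens, possessive clitics, slash
#' lists, comma boundaries, identifier-number ranges, and substance /
#' serotype names that must stay whole.
#'
#' @return List of elements with fields `text` and `gold` (character vector).
#' @export
example_descriptions <- function() {
  list(
    list(text = "Entire upper dental arch (body structure)",
         gold = c("Entire", "upper", "dental", "arch", "(", "body",
                  "structure", ")")),
    list(text = "Royal Navy - non-commissioned personnel (occupation)",
         gold = c("Royal", "Navy", "-", "non-commissioned", "personnel",
                  "(", "occupation", ")")),
    list(text = "Primidone 50mg tablet",
         gold = c("Primidone", "50", "mg", "tablet")),
    list(text = "Primary Sjogren's syndrome with organ/system involvement (disorder)",
         gold = c("Primary", "Sjogren", "'s", "syndrome", "with", "organ",
                  "and", "system", "involvement", "(", "disorder", ")")),
    list(text = "Posterior cervical spinal cord injury, without spinal injury, C1-4",
         gold = c("Posterior", "cervical", "spinal", "cord", "injury", ",",
                  "without", "spinal", "injury", ",", "C1", "to", "4")),
    list(text = "Precorrin-3B C17-methyltransferase",
         gold = c("Precorrin-3B", "C17-methyltransferase")),
    list(text = "Salmonella III arizonae 47:k:1,5,7",
         gold = c("Salmonella", "III", "arizonae", "47:k:1,5,7"))
  )
}

#' Ground-truth HMM parameter sets
#'
#' Explicit generative order-1 HMMs used by the corpus sampler:
#'
#' * `"clinical"`: a 10-tag Penn-style chain over concept-description
#'   vocabulary (drugs, anatomy, qualifiers, doses, measurement units with
#'   their own `NNU` tag, possessive clitics, punctuation; no determiner tag,
#'   as concept descriptions lack articles), structured so that tag
#'   transitions carry the disambiguating signal (e.g. unit -> `IN` is
#'   likely, unit -> `CC` is not).
#' * `"general"`: a 10-tag newspaper-English chain sharing the tag
#'   conventions but with determiners, no unit tag and no clinical
#'   vocabulary; stands in for out-of-domain training text.
#' * `"toy"`: a small 3-tag chain for parameter-recovery checks.
#'
#' @param domain One of `"clinical"`, `"general"`, `"toy"`.
#' @return List with `tags`, `start` (distribution over first tags), `trans`
#'   (row-stochastic matrix) and `emissions` (per-tag named distributions).
#' @export
ground_truth_hmm <- function(domain = c("clinical", "general", "toy")) {
  domain <- match.arg(domain)
  mk <- function(start, rows, emissions) {
    tags <- names(rows)
    trans <- matrix(0, length(tags), length(tags),
                    dimnames = list(tags, tags))
    for (p in tags) trans[p, names(rows[[p]])] <- rows[[p]]
    stopifnot(all(abs(rowSums(trans) - 1) < 1e-9))
    start_v <- stats::setNames(numeric(length(tags)), tags)
    start_v[names(start)] <- start
    stopifnot(abs(sum(start_v) - 1) < 1e-9)
    emissions <- lapply(emissions, normalize_probs)
    stopifnot(setequal(names(emissions), tags))
    list(tags = tags, start = start_v, trans = trans,
         emissions = emissions[tags])
  }
  if (domain == "toy") {
    return(mk(
      start = c(DET = 0.6, NOUN = 0.3, VERB = 0.1),
      rows = list(
        DET  = c(NOUN = 0.7, DET = 0.1, VERB = 0.2),
        NOUN = c(VERB = 0.5, NOUN = 0.3, DET = 0.2),
        VERB = c(DET = 0.5, NOUN = 0.4, VERB = 0.1)
      ),
      emissions = list(
        DET = c(the = 6, a = 4),
        NOUN = c(dog = 3, cat = 3, vet = 2, bone = 2),
        VERB = c(runs = 4, sees = 3, barks = 3)
      )
    ))
  }
  if (domain == "clinical") {
    return(mk(
      start = c(JJ = 0.32, NN = 0.18, NNP = 0.27, CD = 0.10, IN = 0.02,
                NNU = 0.05, PUNCT = 0.06),
      rows = list(
        CC    = c(NN = 0.50, NNP = 0.20, JJ = 0.15, CD = 0.10, NNU = 0.05),
        CD    = c(NNU = 0.45, NN = 0.20, CD = 0.05, TO = 0.10, PUNCT = 0.10,
                  IN = 0.05, CC = 0.05),
        IN    = c(NN = 0.40, NNP = 0.20, NNU = 0.20, JJ = 0.10, CD = 0.10),
        JJ    = c(JJ = 0.25, NN = 0.55, NNP = 0.05, NNU = 0.05, CD = 0.05,
                  PUNCT = 0.05),
        NN    = c(NN = 0.19, IN = 0.15, CC = 0.10, PUNCT = 0.22, POS = 0.06,
                  CD = 0.05, JJ = 0.05, NNP = 0.05, NNU = 0.05, TO = 0.08),
        NNP   = c(NN = 0.30, NNP = 0.15, POS = 0.25, CD = 0.10,
                  PUNCT = 0.10, IN = 0.05, CC = 0.05),
        NNU   = c(IN = 0.35, NN = 0.20, PUNCT = 0.20, CD = 0.10, CC = 0.02,
                  JJ = 0.05, NNP = 0.08),
        POS   = c(NN = 0.60, JJ = 0.30, CD = 0.10),
        PUNCT = c(NN = 0.40, NNP = 0.18, JJ = 0.17, IN = 0.05, CD = 0.08,
                  CC = 0.04, NNU = 0.05, PUNCT = 0.03),
        TO    = c(CD = 0.60, NN = 0.25, NNP = 0.10, NNU = 0.05)
      ),
      emissions = list(
        CC  = c(and = 85, or = 15),
        CD  = c("10" = 3, "50" = 3, "4" = 3, "2" = 2, "5" = 2, "100" = 2,
                "250" = 2, "500" = 2, "1" = 2, "3" = 2, III = 2),
        IN  = c(of = 6, with = 5, without = 4, "in" = 3, per = 2),
        JJ  = c(Entire = 3, upper = 3, dental = 3, Primary = 3,
                Posterior = 3, cervical = 3, spinal = 5, chronic = 5,
                acute = 4, severe = 3, mild = 3, partial = 3, complete = 3,
                "non-commissioned" = 2),
        NN  = c(patient = 4, tablet = 5, syndrome = 4, injury = 6, arch = 3,
                structure = 4, involvement = 3, personnel = 2, cord = 3,
                organ = 10, system = 10, body = 4, occupation = 6,
                disorder = 6, finding = 6, procedure = 5, solution = 4,
                dose = 4, capsule = 3, fracture = 3, C1 = 6, caffeine = 3,
                arizonae = 2, morphology = 2, "Precorrin-3B" = 3,
                "C17-methyltransferase" = 3, "47:k:1,5,7" = 3),
        NNP = c(Primidone = 2, Sjogren = 2, Royal = 1, Navy = 1,
                Paracetamol = 2, Salmonella = 2, Warfarin = 2,
                Metformin = 2),
        NNU = c(mg = 6, ml = 5, g = 3, kg = 2, mcg = 2, units = 2),
        POS = c("'s" = 1),
        PUNCT = c("," = 22, "." = 16, "(" = 28, ")" = 28, "-" = 4, ":" = 2),
        TO  = c(to = 1)
      )
    ))
  }
  mk(  # general newspaper English, no clinical vocabulary, no unit tag
    start = c(DT = 0.25, NNP = 0.25, JJ = 0.15, NN = 0.15, IN = 0.05,
              CD = 0.05, PUNCT = 0.05, CC = 0.05),
    rows = list(
      CC    = c(NN = 0.35, NNP = 0.20, JJ = 0.15, DT = 0.15, CD = 0.10,
                IN = 0.05),
      CD    = c(NN = 0.50, PUNCT = 0.15, IN = 0.10, CD = 0.10, TO = 0.10,
                CC = 0.05),
      DT    = c(NN = 0.55, JJ = 0.30, NNP = 0.10, CD = 0.05),
      IN    = c(DT = 0.35, NN = 0.25, NNP = 0.20, JJ = 0.10, CD = 0.10),
      JJ    = c(NN = 0.60, JJ = 0.20, PUNCT = 0.10, CC = 0.05, CD = 0.05),
      NN    = c(IN = 0.25, PUNCT = 0.25, NN = 0.15, CC = 0.10, TO = 0.10,
                POS = 0.05, CD = 0.05, DT = 0.05),
      NNP   = c(NNP = 0.20, POS = 0.20, NN = 0.15, PUNCT = 0.15, IN = 0.15,
                CC = 0.05, TO = 0.05, CD = 0.05),
      POS   = c(NN = 0.55, JJ = 0.30, NNP = 0.10, CD = 0.05),
      PUNCT = c(DT = 0.20, NNP = 0.20, NN = 0.20, JJ = 0.10, IN = 0.10,
                CC = 0.10, CD = 0.05, PUNCT = 0.05),
      TO    = c(NN = 0.30, DT = 0.30, NNP = 0.20, CD = 0.20)
    ),
    emissions = list(
      CC  = c(and = 7, but = 2, or = 1),
      CD  = c("1969" = 2, "30" = 2, million = 2, two = 2, three = 1,
              "15" = 1),
      DT  = c(the = 5, The = 2, a = 2, an = 1),
      IN  = c(of = 6, "in" = 5, on = 3, with = 3, "for" = 3),
      JJ  = c(new = 2, big = 1, former = 1, political = 1, financial = 1,
              public = 1, strong = 1, early = 1),
      NN  = c(market = 1, company = 1, government = 1, year = 1, share = 1,
              president = 1, report = 1, plan = 1, rate = 1, time = 1,
              week = 1, group = 1),
      NNP = c(Washington = 1, Congress = 1, Tuesday = 1, Japan = 1,
              Smith = 1, London = 1),
      POS = c("'s" = 1),
      PUNCT = c("," = 35, "." = 35, "\"" = 10, "(" = 10, ")" = 10),
      TO  = c(to = 1)
    )
  )
}

#' Fixture generation settings
#'
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param n_units Number of evaluation units to generate.
#' @param ambiguity_rate Proportion of units containing at least one
#'   ambiguous token boundary; the count is `floor(rate * n_units + 0.5)`,
#'   achieved exactly by construction.
#' @param domain_mix Proportion of training sentences drawn from the
#'   clinical chain (vs the general-English chain); 1 is fully in-domain, 0
#'   fully out-of-domain.
#' @param n_sentences Number of training sentences to sample.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 42L, n_units = 500L, ambiguity_rate = 0.455,
                         domain_mix = 1, n_sentences = 1200L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!is.numeric(ambiguity_rate) || ambiguity_rate < 0 ||
      ambiguity_rate > 1) {
    stop("ambiguity_rate must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(domain_mix) || domain_mix < 0 || domain_mix > 1) {
    stop("domain_mix must be in [0, 1]", call. = FALSE)
  }
  stopifnot(n_units >= 1L, n_sentences >= 1L)
  structure(list(seed = as.integer(seed), n_units = as.integer(n_units),
                 ambiguity_rate = ambiguity_rate, domain_mix = domain_mix,
                 n_sentences = as.integer(n_sentences)),
            class = "fixture_spec")
}

#' Sample a tagged corpus from a ground-truth HMM
#'
#' Draws tag sequences from the chain (first tag from the start
#' distribution, then one-step transitions) and tokens from the per-tag
#' emission distributions. Sentence lengths are uniform on `len_range`.
#' Caller is responsible for seeding (see [generate_tagged_corpus()]).
#'
#' @param hmm A parameter set from [ground_truth_hmm()].
#' @param n_sentences Number of sentences.
#' @param len_range Inclusive sentence-length bounds.
#' @return List of tagged sentences (data frames with `token`, `tag`).
#' @export
sample_hmm_corpus <- function(hmm, n_sentences, len_range = c(6L, 12L)) {
  lapply(seq_len(n_sentences), function(i) {
    len <- sample(len_range[1L]:len_range[2L], 1L)
    tg <- character(len)
    tg[1L] <- draw1(hmm$start)
    for (j in seq_len(len - 1L)) {
      tg[j + 1L] <- draw1(hmm$trans[tg[j], ])
    }
    tok <- vapply(tg, function(t) draw1(hmm$emissions[[t]]), character(1))
    data.frame(token = unname(tok), tag = tg, stringsAsFactors = FALSE)
  })
}

#' Generate a tagged training corpus
#'
#' Samples slash-format-ready tagged sentences from the ground-truth HMMs:
#' each sentence comes from the clinical chain with probability
#' `spec$domain_mix` and from the general-English chain otherwise, emulating
#' in-domain vs out-of-domain training material. The ground-truth parameters
#' are returned alongside for parameter-recovery checks.
#'
#' @param spec A [fixture_spec()].
#' @return List with `sentences` (list of tagged data frames) and `truth`
#'   (the [ground_truth_hmm()] parameter sets used).
#' @export
generate_tagged_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  clinical <- ground_truth_hmm("clinical")
  general <- ground_truth_hmm("general")
  sentences <- with_seed(spec$seed + 1L, {
    domains <- stats::runif(spec$n_sentences) < spec$domain_mix
    lapply(seq_len(spec$n_sentences), function(i) {
      sample_hmm_corpus(if (domains[i]) clinical else general, 1L)[[1L]]
    })
  })
  list(sentences = sentences,
       truth = list(clinical = clinical, general = general))
}

# Evaluation-unit templates. Each returns list(text, gold, ambiguous).
eval_templates <- function() {
  jj <- c("chronic", "acute", "severe", "mild", "partial", "complete",
          "cervical", "spinal")
  nn <- c("injury", "fracture", "syndrome", "disorder", "involvement",
          "morphology")
  drug <- c("Primidone", "Paracetamol", "Warfarin", "Metformin")
  num <- c("10", "50", "100", "250", "500", "2", "5")
  unit <- c("mg", "ml", "g", "kg", "mcg")
  semtag <- c("disorder", "finding", "occupation", "procedure")
  pick <- function(x) sample(x, 1L)
  list(
    ambiguous = list(
      function() {  # fused dose: "Primidone 50mg tablet"
        d <- pick(drug); n <- pick(num); u <- pick(unit)
        list(text = paste0(d, " ", n, u, " tablet"),
             gold = c(d, n, u, "tablet"))
      },
      function() {  # possessive clitic
        j <- pick(c("Primary", "chronic", "acute")); h <- pick(nn)
        list(text = paste0(j, " Sjogren's ", h),
             gold = c(j, "Sjogren", "'s", h))
      },
      function() {  # parenthesized semantic tag
        j <- pick(jj); h <- pick(nn); s <- pick(semtag)
        list(text = paste0(j, " ", h, " (", s, ")"),
             gold = c(j, h, "(", s, ")"))
      },
      function() {  # identifier-number range with comma boundary
        j <- pick(jj); h <- pick(nn); d <- pick(c("2", "3", "4", "5"))
        list(text = paste0(j, " ", h, ", C1-", d),
             gold = c(j, h, ",", "C1", "to", d))
      },
      function() {  # unit slash read as "per"
        d <- pick(drug); n <- pick(num)
        us <- sample(unit, 2L)
        list(text = paste0(d, " ", n, " ", us[1L], "/", us[2L], " solution"),
             gold = c(d, n, us[1L], "per", us[2L], "solution"))
      },
      function() {  # plus list read as "and"
        d <- pick(drug)
        list(text = paste0(d, " + caffeine"), gold = c(d, "and", "caffeine"))
      }
    ),
    plain = list(
      function() {
        w <- c(pick(jj), pick(jj), pick(nn))
        list(text = paste(w, collapse = " "), gold = w)
      },
      function() {
        w <- c(pick(nn), "of", pick(jj), pick(nn))
        list(text = paste(w, collapse = " "), gold = w)
      },
      function() {
        w <- c(pick(jj), pick(nn), "with", pick(nn))
        list(text = paste(w, collapse = " "), gold = w)
      },
      function() {
        w <- c(pick(drug), pick(c("tablet", "capsule", "solution")))
        list(text = paste(w, collapse = " "), gold = w)
      }
    )
  )
}

#' Generate a synthetic evaluation set
#'
#' Instantiates concept-description templates with seeded vocabulary and
#' constructs each unit's gold token sequence alongside its text (quantities
#' split, possessives split, closed-class expansions applied). Exactly
#' `floor(ambiguity_rate * n_units + 0.5)` units contain an ambiguous token
#' boundary (fused dose, possessive, parenthesized tag, range, unit slash,
#' or plus list), cycled over the ambiguous templates so every construct is
#' represented; the remainder are tokenizable by whitespace alone. Every
#' gold sequence is reachable in the default transducer set's lattice by
#' construction.
#'
#' @param spec A [fixture_spec()].
#' @return List with `units` (list of [text_unit()]), `gold` (named list of
#'   token vectors) and `ambiguous` (named logical).
#' @export
generate_eval_set <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_units
  n_amb <- as.integer(floor(spec$ambiguity_rate * n + 0.5))
  with_seed(spec$seed + 2L, {
    tpl <- eval_templates()
    kinds <- c(rep(TRUE, n_amb), rep(FALSE, n - n_amb))
    kinds <- sample(kinds)
    amb_i <- 0L; plain_i <- 0L
    units <- vector("list", n); gold <- vector("list", n)
    ids <- sprintf("u%04d", seq_len(n))
    for (i in seq_len(n)) {
      if (kinds[i]) {
        amb_i <- amb_i + 1L
        f <- tpl$ambiguous[[((amb_i - 1L) %% length(tpl$ambiguous)) + 1L]]
      } else {
        plain_i <- plain_i + 1L
        f <- tpl$plain[[((plain_i - 1L) %% length(tpl$plain)) + 1L]]
      }
      item <- f()
      units[[i]] <- text_unit(item$text, ids[i])
      gold[[i]] <- item$gold
    }
    list(units = units, gold = stats::setNames(gold, ids),
         ambiguous = stats::setNames(kinds, ids))
  })
}
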