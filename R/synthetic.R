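## Synthetic ADE-narrative generator.
##
## Emulates the structure of Chinese adverse-drug-event report narratives:
## a reason for medication (disease / symptom / treatment), a drug
## administration (generic names and mixed-script abbreviations such as
## "10% GS"), an adverse-reaction onset, and an outcome, embedded in
## connective clinical filler. Every lexicon item placed is recorded as an
## entity span whose text slice equals the lexicon surface form exactly.
## The generator is structural: it makes the tagger, decoder and scorer
## testable without confidential corpora, and does not attempt clinical or
## epidemiological realism.

#' Default entity lexicons for the synthetic generator
#'
#' @return Named list with non-empty `Reason`, `Drug`, and `ADR` character
#'   vectors.
#' @export
default_lexicons <- function() {
  list(
    Reason = c("高血压", "糖尿病", "肺部感染",
               "上呼吸道感染", "冠心病",
               "急性胃肠炎", "支气管炎",
               "尿路感染", "术后发热",
               "失眠", "偏头痛", "胃炎"),
    Drug = c("阿莫西林", "头孢呋辛",
             "奥美拉唑", "青霉素",
             "左氧氟沙星", "阿司匹林",
             "布洛芬", "地塞米松",
             "胰岛素", "氯化钠注射液",
             "10% GS", "0.9% NS", "葡萄糖注射液",
             "维生素C"),
    ADR = c("头痛", "恶心", "呕吐", "皮疹",
            "瘙痒", "头晕", "腹泻", "发热",
            "寒战", "心悸", "胸闷", "乏力",
            "面部红肿", "过敏性休克",
            "口干")
  )
}

#' Default narrative templates
#'
#' Each template is a skeleton with typed slots following the canonical
#' report structure: reason, drug administration, ADR onset, outcome.
#'
#' @return Character vector of templates with `{Reason}`, `{Drug}`, `{ADR}`
#'   slots.
#' @export
default_templates <- function() {
  c("患者因{Reason}使用{Drug}后出现{ADR}，停药后好转。",
    "患者既往有{Reason}，给予{Drug}静脉滴注，次日出现{ADR}。",
    "因{Reason}口服{Drug}，约30分钟后出现{ADR}及{ADR}，对症处理后缓解。",
    "患者诊断为{Reason}，应用{Drug}治疗期间出现{ADR}，考虑药物不良反应。",
    "患者因{Reason}就诊，医嘱予{Drug}，用药第2天出现{ADR}，停药并观察。",
    "使用{Drug}联合{Drug}治疗{Reason}，出现{ADR}，经处理后症状消失。",
    "患者因{Reason}入院，静脉滴注{Drug}约10分钟后出现{ADR}，立即停药，症状逐渐缓解。",
    "给予{Drug}治疗{Reason}，患者出现{ADR}伴{ADR}，减量后症状减轻。")
}

## Distractor snippets inserted as noise between narrative pieces.
noise_snippets <- function() {
  c("血压监测正常，", "复查血常规无异常，",
    "随访无异常，", "体温39度，",
    "患者无明显不适，")
}

#' Configuration of the synthetic corpus generator
#'
#' Identical config + seed regenerates a byte-identical corpus.
#'
#' @param n_docs Number of documents (default 250: the package's standard
#'   200-train / 50-test working scale).
#' @param seed Integer seed.
#' @param lexicons Named list of `Reason` / `Drug` / `ADR` surface strings.
#' @param templates Character vector of slotted narrative skeletons.
#' @param noise_rate Probability of inserting a distractor snippet at each
#'   piece boundary (default 0.1).
#' @param length_range Admissible document lengths in characters; documents
#'   falling outside are redrawn.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_docs = 250L, seed = 1L,
                             lexicons = default_lexicons(),
                             templates = default_templates(),
                             noise_rate = 0.1,
                             length_range = c(10L, 510L)) {
  stopifnot(n_docs >= 1, noise_rate >= 0, noise_rate <= 1,
            length(length_range) == 2, length_range[1] <= length_range[2],
            length(templates) >= 1)
  for (ty in entity_types()) {
    if (length(lexicons[[ty]]) == 0) stop("empty lexicon for type ", ty)
  }
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 lexicons = lexicons, templates = templates,
                 noise_rate = noise_rate,
                 length_range = as.integer(length_range)),
            class = "generator_config")
}

parse_template <- function(tpl) {
  # split a template into literal pieces and typed slots, in order
  m <- gregexpr("\\{(Reason|Drug|ADR)\\}", tpl)[[1]]
  pieces <- list()
  pos <- 1L
  if (m[1] != -1L) {
    for (k in seq_along(m)) {
      s <- m[k]; len <- attr(m, "match.length")[k]
      if (s > pos) pieces[[length(pieces) + 1L]] <-
          list(kind = "lit", text = substr(tpl, pos, s - 1L))
      pieces[[length(pieces) + 1L]] <-
        list(kind = "slot", etype = substr(tpl, s + 1L, s + len - 2L))
      pos <- s + len
    }
  }
  if (pos <= nchar(tpl)) pieces[[length(pieces) + 1L]] <-
      list(kind = "lit", text = substring(tpl, pos))
  pieces
}

fill_template <- function(cfg, tpl, doc_id) {
  pieces <- parse_template(tpl)
  texts <- character(0)
  etype <- character(0); start <- integer(0); end <- integer(0)
  off <- 0L
  for (piece in pieces) {
    if (cfg$noise_rate > 0 && stats::runif(1) < cfg$noise_rate) {
      snip <- sample(noise_snippets(), 1L)
      texts <- c(texts, snip); off <- off + nchar(snip)
    }
    if (piece$kind == "lit") {
      texts <- c(texts, piece$text)
      off <- off + nchar(piece$text)
    } else {
      surface <- sample(cfg$lexicons[[piece$etype]], 1L)
      texts <- c(texts, surface)
      etype <- c(etype, piece$etype)
      start <- c(start, off); end <- c(end, off + nchar(surface))
      off <- off + nchar(surface)
    }
  }
  ann_doc(doc_id, paste(texts, collapse = ""), entity_spans(etype, start, end))
}

#' Generate a synthetic annotated ADE corpus
#'
#' @param cfg A [generator_config()].
#' @return List of `cfg$n_docs` [ann_doc()] objects with ids `syn0001`, ...
#' @export
generate_corpus <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_local_seed(cfg$seed, {
    lapply(seq_len(cfg$n_docs), function(i) {
      id <- sprintf("syn%04d", i)
      for (try in 1:100) {
        tpl <- sample(cfg$templates, 1L)
        doc <- fill_template(cfg, tpl, id)
        n <- nchar(doc$text)
        if (n >= cfg$length_range[1] && n <= cfg$length_range[2]) return(doc)
      }
      stop("could not draw a document inside length_range after 100 tries")
    })
  })
}

#' Partition a corpus into train / test / validation subsets
#'
#' Deterministic split by position: the first `n_train` documents train, the
#' next `n_test` test, and the remainder is the validation set.
#'
#' @param docs List of documents (any type).
#' @param n_train,n_test Subset sizes; must satisfy
#'   `n_train + n_test <= length(docs)`.
#' @return List with `train`, `test`, `validation`.
#' @export
partition_corpus <- function(docs, n_train, n_test) {
  n <- length(docs)
  stopifnot(n_train >= 0, n_test >= 0, n_train + n_test <= n)
  list(train = docs[seq_len(n_train)],
       test = docs[n_train + seq_len(n_test)],
       validation = if (n_train + n_test < n)
         docs[(n_train + n_test + 1L):n] else docs[0])
}

#' Corrupt gold annotations to emulate an imperfect human annotator
#'
#' Each span is independently left intact with probability
#' `1 - error_rate`; otherwise one error kind is drawn from `weights`:
#' `drop` (span removed), `shift` (one boundary moved by one character), or
#' `swap` (entity type replaced by a different one). A shift that would
#' leave the document invalid (out of bounds or overlapping) degrades to a
#' drop. Used to exercise the man-machine comparison harness.
#'
#' @param docs List of [ann_doc()].
#' @param error_rate Per-span corruption probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param weights Named numeric vector over `c("drop", "shift", "swap")`;
#'   normalized internally.
#' @return List of corrupted [ann_doc()] with unchanged ids and texts.
#' @export
corrupt_annotations <- function(docs, error_rate, seed = 1L,
                                weights = c(drop = 1, shift = 1, swap = 1)) {
  stopifnot(error_rate >= 0, error_rate <= 1,
            all(names(weights) %in% c("drop", "shift", "swap")),
            sum(weights) > 0)
  w <- weights / sum(weights)
  with_local_seed(seed, lapply(docs, function(doc) {
    n <- nchar(doc$text)
    e <- doc$entities
    keep <- rep(TRUE, nrow(e))
    for (i in seq_len(nrow(e))) {
      if (stats::runif(1) >= error_rate) next
      kind <- sample(names(w), 1L, prob = w)
      if (kind == "drop") {
        keep[i] <- FALSE
      } else if (kind == "swap") {
        e$etype[i] <- sample(setdiff(entity_types(), e$etype[i]), 1L)
      } else {
        cand <- e
        side <- sample(c("start", "end"), 1L)
        delta <- sample(c(-1L, 1L), 1L)
        cand[[side]][i] <- cand[[side]][i] + delta
        ok <- cand$start[i] >= 0 && cand$start[i] < cand$end[i] && cand$end[i] <= n
        if (ok) {
          others <- cand[-i, , drop = FALSE]
          ok <- !any(others$start < cand$end[i] & cand$start[i] < others$end)
        }
        if (ok) e <- cand else keep[i] <- FALSE
      }
    }
    ann_doc(doc$doc_id, doc$text,
            e[keep, , drop = FALSE])
  }))
}
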