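# RNA application models: multitarget sequence design over base-pair
# energies and GC content, plus DFA-based motif control (Aho-Corasick).

#' RNA alphabet and canonical base pairs
#'
#' Nucleotides are encoded as integers A=1, C=2, G=3, U=4.  The canonical
#' pair set is \{AU, CG, GC, GU, UA, UG\}.
#' @export
RNA_ALPHABET <- c("A", "C", "G", "U")

.CANONICAL <- matrix(c(1L, 4L,  2L, 3L,  3L, 2L,  3L, 4L,  4L, 1L,  4L, 3L),
                     ncol = 2L, byrow = TRUE,
                     dimnames = list(c("AU", "CG", "GC", "GU", "UA", "UG"),
                                     NULL))

#' Encode/decode RNA sequences as integer codes
#'
#' `T` is accepted on input and normalized to `U`.
#' @param x character string (or vector of single letters) / integer codes
#' @export
rnaToCodes <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  x <- toupper(x)
  x[x == "T"] <- "U"
  codes <- match(x, RNA_ALPHABET)
  if (anyNA(codes))
    .tfStop(paste("alien symbol in RNA sequence:",
                  paste(unique(x[is.na(codes)]), collapse = ", ")),
            "treefeat_alphabet_error")
  codes
}

#' @rdname rnaToCodes
#' @export
codesToRna <- function(x) paste(RNA_ALPHABET[x], collapse = "")

#' Is a pair of nucleotide codes canonical?
#' @param a,b integer codes (vectors allowed)
#' @export
isCanonicalPair <- function(a, b) {
  paste0(RNA_ALPHABET[a], RNA_ALPHABET[b]) %in% rownames(.CANONICAL)
}

#' Construct a secondary structure from explicit pairs
#' @param length sequence length
#' @param pairs two-column matrix of (i, j) pairs with i < j (may be empty)
#' @export
secondaryStructure <- function(length, pairs = matrix(integer(0), 0, 2)) {
  p <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(p)) p <- p[order(p[, 1L]), , drop = FALSE]
  new("SecondaryStructure", length = as.integer(length), pairs = p)
}

#' Are any two pairs of a structure crossing?
#' @param s a [SecondaryStructure-class]
#' @export
isCrossing <- function(s) {
  p <- s@pairs
  if (nrow(p) < 2L) return(FALSE)
  for (a in seq_len(nrow(p) - 1L)) for (b in (a + 1L):nrow(p)) {
    i <- p[a, 1L]; j <- p[a, 2L]; k <- p[b, 1L]; l <- p[b, 2L]
    if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) return(TRUE)
  }
  FALSE
}

#' Parse a dot-bracket string into a secondary structure
#'
#' Bracket layers `()`, `[]`, `{}` and `<>` are matched independently by
#' per-layer stacks, so crossing (pseudoknotted) structures can be written
#' with several layers.  Unbalanced brackets and doubly-paired positions are
#' errors.
#'
#' @param text dot-bracket string; `.` (and `-`, `_`) denote unpaired
#' @return a [SecondaryStructure-class]
#' @examples
#' parseDotBracket("((..))")@pairs
#' isCrossing(parseDotBracket("([)]"))
#' @export
parseDotBracket <- function(text) {
  chars <- strsplit(text, "")[[1]]
  open <- c("(", "[", "{", "<")
  close <- c(")", "]", "}", ">")
  stacks <- rep(list(integer(0)), 4L)
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% c(".", "-", "_")) next
    oi <- match(ch, open)
    if (!is.na(oi)) { stacks[[oi]] <- c(stacks[[oi]], i); next }
    ci <- match(ch, close)
    if (is.na(ci))
      .tfStop(paste("unexpected character in dot-bracket:", ch),
              "treefeat_parse_error")
    if (length(stacks[[ci]]) == 0L)
      .tfStop("unbalanced dot-bracket: unmatched closing bracket",
              "treefeat_parse_error")
    j <- stacks[[ci]][length(stacks[[ci]])]
    stacks[[ci]] <- stacks[[ci]][-length(stacks[[ci]])]
    pairs <- rbind(pairs, c(j, i))
  }
  if (any(lengths(stacks) > 0L))
    .tfStop("unbalanced dot-bracket: unmatched opening bracket",
            "treefeat_parse_error")
  secondaryStructure(length(chars), pairs)
}

#' Base-pair energy table
#'
#' The numeric defaults are configurable placeholders (stacking strength
#' ordering GC > AU > GU), not a calibrated thermodynamic parameter set; all
#' quantitative work should pass an explicit table.
#'
#' @param GC,CG,AU,UA,GU,UG energy per pair type
#' @return named numeric over the canonical pair types
#' @export
bpEnergyTable <- function(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1) {
  c(AU = AU, CG = CG, GC = GC, GU = GU, UA = UA, UG = UG)
}

#' GC count of an RNA sequence
#' @param sequence string over A, C, G, U (T accepted)
#' @export
gcCount <- function(sequence) {
  codes <- rnaToCodes(sequence)
  sum(codes == 2L | codes == 3L)
}

#' Base-pair energy of a sequence on a structure
#'
#' Sum of table entries over the structure's pairs; `+Inf` if any pair is
#' non-canonical in the sequence.
#'
#' @param sequence RNA string
#' @param structure a [SecondaryStructure-class] (or dot-bracket string)
#' @param table a [bpEnergyTable()]
#' @export
bpEnergy <- function(sequence, structure, table = bpEnergyTable()) {
  if (is.character(structure)) structure <- parseDotBracket(structure)
  codes <- rnaToCodes(sequence)
  p <- structure@pairs
  if (nrow(p) == 0L) return(0)
  pt <- paste0(RNA_ALPHABET[codes[p[, 1L]]], RNA_ALPHABET[codes[p[, 2L]]])
  if (!all(pt %in% names(table))) return(Inf)
  sum(table[pt])
}

.BPCompl <- defineConstraintType("BPCompl", function(v)
  isCanonicalPair(v[1], v[2]))
.GCf <- defineFunctionType("GC", function(v) as.numeric(v == 2L | v == 3L))
.BPEnergyF <- defineFunctionType("BPEnergy", function(v, table) {
  pt <- paste0(RNA_ALPHABET[v[1]], RNA_ALPHABET[v[2]])
  if (pt %in% names(table)) unname(table[pt]) else Inf
})

#' Multitarget RNA design model
#'
#' Builds the feature network for sampling/optimizing RNA sequences of
#' length `n` against one or more target secondary structures: one variable
#' per position (domain A, C, G, U), one canonical-base-pair constraint
#' `BPCompl` per pair in the union of the targets, a feature `gc` of unary
#' GC indicator functions, and one energy feature `E1, E2, ...` per target
#' structure summing `BPEnergy` over its pairs.  Sampling at weights
#' `(alpha_gc, alpha_1, ..., alpha_k)` then follows
#' `P(s) propto exp(alpha_gc #GC(s)) prod_l exp(alpha_l E(s, S_l))`.
#'
#' @param structures list of [SecondaryStructure-class] (or dot-bracket
#'   strings), all of the same length
#' @param n sequence length (inferred from the structures if missing)
#' @param table a [bpEnergyTable()]
#' @param allowCrossing permit crossing (pseudoknotted) targets; the strict
#'   default rejects them, matching the noncrossing multitarget problem
#'   statement (the engine itself handles crossing inputs)
#' @return a [FeatureNetwork-class]
#' @export
designModel <- function(structures, n = NULL, table = bpEnergyTable(),
                        allowCrossing = FALSE) {
  if (!is.list(structures)) structures <- list(structures)
  structures <- lapply(structures, function(s)
    if (is.character(s)) parseDotBracket(s) else s)
  lens <- vapply(structures, function(s) s@length, 0L)
  if (is.null(n)) n <- lens[1]
  if (any(lens != n))
    .tfStop("structure length mismatch", "treefeat_parse_error")
  if (!allowCrossing && any(vapply(structures, isCrossing, TRUE)))
    .tfStop("crossing target structure (use allowCrossing = TRUE)",
            "treefeat_parse_error")
  net <- addVariables(featureNetwork(), n, 1:4)
  allPairs <- unique(do.call(rbind, lapply(structures, function(s) s@pairs)))
  if (!is.null(allPairs) && nrow(allPairs))
    for (r in seq_len(nrow(allPairs)))
      net <- addConstraint(net, .BPCompl(allPairs[r, ]))
  net <- addFunctions(net, "gc", lapply(seq_len(n), function(i) .GCf(i)))
  for (l in seq_along(structures)) {
    p <- structures[[l]]@pairs
    if (nrow(p))
      net <- addFunctions(net, paste0("E", l),
                          lapply(seq_len(nrow(p)), function(r)
                            .BPEnergyF(p[r, ], table = table)))
    else net <- addFunctions(net, paste0("E", l))
  }
  net
}

# ---- deterministic finite automata -----------------------------------------

#' Aho-Corasick motif automaton
#'
#' Builds a DFA from a motif list by the trie + failure-link construction,
#' with all motif-ending states merged into a single absorbing state.  In
#' `accept` mode the language is the words containing at least one motif
#' occurrence (so with word length equal to the motif length, exactly the
#' motif set); in `forbid` mode the acceptance is complemented (every state
#' but the absorbing one accepts), i.e. words avoiding all motifs.
#'
#' @param motifs character vector of motif words
#' @param alphabet symbol set (default RNA)
#' @param mode `"accept"` or `"forbid"`
#' @return a [DFA-class]
#' @examples
#' dfa <- ahoCorasickDfa(c("UGA", "UUA", "UUG"))  # 5 states
#' dfaAccepts(dfa, "UGA")
#' @export
ahoCorasickDfa <- function(motifs, alphabet = RNA_ALPHABET,
                           mode = c("accept", "forbid")) {
  mode <- match.arg(mode)
  if (any(nchar(motifs) == 0L)) .tfStop("empty motif", "treefeat_parse_error")
  sig <- length(alphabet)
  mot <- lapply(motifs, function(m) {
    codes <- match(strsplit(toupper(m), "")[[1]], alphabet)
    if (anyNA(codes)) .tfStop(paste("motif symbol outside alphabet:", m),
                              "treefeat_alphabet_error")
    codes
  })
  # trie: state 1 = root
  goto <- matrix(0L, 1L, sig)
  isEnd <- FALSE
  for (m in mot) {
    q <- 1L
    for (a in m) {
      if (goto[q, a] == 0L) {
        goto <- rbind(goto, rep(0L, sig))
        isEnd <- c(isEnd, FALSE)
        goto[q, a] <- nrow(goto)
      }
      q <- goto[q, a]
    }
    isEnd[q] <- TRUE
  }
  nTrie <- nrow(goto)
  # BFS failure links; delta = completed transition function
  fail <- rep(1L, nTrie)
  delta <- goto
  queue <- integer(0)
  for (a in seq_len(sig)) {
    q <- goto[1L, a]
    if (q == 0L) delta[1L, a] <- 1L else { fail[q] <- 1L; queue <- c(queue, q) }
  }
  while (length(queue)) {
    q <- queue[1L]; queue <- queue[-1L]
    isEnd[q] <- isEnd[q] || isEnd[fail[q]]
    for (a in seq_len(sig)) {
      t <- goto[q, a]
      if (t == 0L) delta[q, a] <- delta[fail[q], a]
      else { fail[t] <- delta[fail[q], a]; queue <- c(queue, t) }
    }
  }
  # collapse motif-ending states into one absorbing state
  keep <- which(!isEnd)
  newId <- integer(nTrie)
  newId[keep] <- seq_along(keep)
  absorb <- length(keep) + 1L
  newId[isEnd] <- absorb
  tr <- matrix(absorb, absorb, sig)
  for (q in keep) tr[newId[q], ] <- newId[delta[q, ]]
  accepting <- if (mode == "accept") absorb else seq_along(keep)
  new("DFA", nStates = absorb, alphabet = alphabet, transition = tr,
      initial = 1L, accepting = as.integer(accepting))
}

#' Run a DFA on a word
#' @param dfa a [DFA-class]
#' @param word character string over the DFA alphabet
#' @return `TRUE` iff the word is accepted
#' @export
dfaAccepts <- function(dfa, word) {
  codes <- if (nchar(word) == 0L) integer(0)
           else match(strsplit(toupper(word), "")[[1]], dfa@alphabet)
  if (anyNA(codes)) .tfStop("symbol outside DFA alphabet",
                            "treefeat_alphabet_error")
  q <- dfa@initial
  for (a in codes) q <- dfa@transition[q, a]
  q %in% dfa@accepting
}

.Transition <- defineConstraintType("Transition", function(v, transition)
  v[3] == transition[v[2], v[1]])

#' Feature network of the words of length n accepted by a DFA
#'
#' Variables `X_1..X_n` (symbols, domain `1..|alphabet|`) and `Y_0..Y_n`
#' (states), with `Y_0` fixed to the initial state, `Y_n` restricted to the
#' accepting states, and one ternary `Transition` constraint per position
#' enforcing `y_i = delta(y_{i-1}, x_i)`.  A pure CSP (no features); its
#' partition function at zero weights counts the accepted words.  When an
#' existing network `into` is given (e.g. an RNA design model whose first
#' `n` variables are the sequence positions), the state variables and
#' constraints are merged into it instead, composing motif control with the
#' other model's constraints and features.
#'
#' @param dfa a [DFA-class]
#' @param n word length (>= 1)
#' @param into optional [FeatureNetwork-class] whose variables `1..n` encode
#'   the word symbols
#' @return a [FeatureNetwork-class]; the state variables are the last
#'   `n + 1` variables
#' @export
dfaModel <- function(dfa, n, into = NULL) {
  n <- as.integer(n)
  if (n < 1L) .tfStop("word length must be >= 1", "treefeat_domain_error")
  if (length(dfa@accepting) == 0L)
    .tfStop("DFA has no accepting state", "treefeat_domain_error")
  net <- if (is.null(into)) addVariables(featureNetwork(), n,
                                         seq_along(dfa@alphabet))
         else into
  base <- nVariables(net)
  net <- addVariables(net, 1L, dfa@initial)                 # Y_0
  if (n > 1L) net <- addVariables(net, n - 1L, seq_len(dfa@nStates))
  net <- addVariables(net, 1L, sort(dfa@accepting))          # Y_n
  for (i in seq_len(n))
    net <- addConstraint(net, .Transition(c(i, base + i, base + i + 1L),
                                          transition = dfa@transition))
  net
}

setMethod("show", "DFA", function(object) {
  cat(sprintf("DFA: %d states over {%s}, %d accepting\n", object@nStates,
              paste(object@alphabet, collapse = ","), length(object@accepting)))
})

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure: length %d, %d pairs%s\n", object@length,
              nrow(object@pairs), if (isCrossing(object)) " (crossing)" else ""))
})
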