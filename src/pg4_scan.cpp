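#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Matcher for the quadruplex pattern
//   (G{3} [ACGT]{min_loop,max_loop}){min_tracts-1,} G{3}
//
// Two search orders are implemented:
//
// * PCRE mode (exact_iters < 0): replicates a backtracking regex engine
//   exactly -- the repeated group is greedy (another iteration attempted
//   before exiting the group), each loop token is greedy (longest length
//   first).  Used to locate match SPANS, which therefore agree with any
//   standard engine's leftmost non-overlapping greedy matches.
//
// * exact-iteration mode (exact_iters = T >= min): the group must repeat
//   exactly T times, loop tokens greedy.  Scanning a matched span with T
//   descending from its maximum gives the stem/loop tokenization that
//   maximizes the tract count first and then takes each loop longest-first,
//   so a G-run longer than three contributes its 5'-most three Gs to the
//   stem and the surplus to the adjacent loop, and a motif of five or more
//   well-separated tracts is recorded with its true tract count.

namespace {

struct Matcher {
  const char *s;
  int L, min_loop, max_loop, min_iters; // min_iters = min_tracts - 1
  bool anchored;                        // require the match to end at L
  int exact_iters;                      // -1 = PCRE mode
  // failure memo keyed by (pos, capped iteration count)
  std::vector<uint8_t> fail;
  std::vector<std::pair<int, int> > loops; // (start, len) of each loop token
  int match_end;

  Matcher(const char *s_, int L_, int min_loop_, int max_loop_,
          int min_tracts_, bool anchored_, int exact_iters_)
      : s(s_), L(L_), min_loop(min_loop_), max_loop(max_loop_),
        min_iters(min_tracts_ - 1), anchored(anchored_),
        exact_iters(exact_iters_), match_end(-1) {
    int depth = (exact_iters >= 0 ? exact_iters : min_iters) + 1;
    fail.assign((size_t)depth * (L + 1), 0);
  }

  static bool is_acgt(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
  }
  bool stem_at(int p) const {
    return p + 3 <= L && s[p] == 'G' && s[p + 1] == 'G' && s[p + 2] == 'G';
  }
  bool may_iterate(int iters) const {
    return exact_iters < 0 || iters < exact_iters;
  }
  bool may_exit(int iters) const {
    return exact_iters < 0 ? iters >= min_iters : iters == exact_iters;
  }

  // continuation from pos after `iters` completed (stem+loop) units
  bool cont(int pos, int iters) {
    int cap = exact_iters >= 0 ? exact_iters : min_iters;
    int key_iters = iters > cap ? cap : iters;
    size_t key = (size_t)key_iters * (L + 1) + pos;
    if (fail[key]) return false;
    if (stem_at(pos)) {
      if (may_iterate(iters)) {
        int lp = pos + 3;
        int maxlen = max_loop < (L - lp) ? max_loop : (L - lp);
        int valid = 0;
        while (valid < maxlen && is_acgt(s[lp + valid])) ++valid;
        for (int len = (maxlen < valid ? maxlen : valid); len >= min_loop;
             --len) {
          loops.push_back(std::make_pair(lp, len));
          if (cont(lp + len, iters + 1)) return true;
          loops.pop_back();
        }
      }
      if (may_exit(iters) && (!anchored || pos + 3 == L)) {
        match_end = pos + 3;
        return true;
      }
    }
    fail[key] = 1;
    return false;
  }
};

// tract-count-maximizing anchored tokenization of a full motif string;
// returns loop (start, len) pairs or empty on failure
bool tokenize_span(const char *s, int L, int min_loop, int max_loop,
                   int min_tracts,
                   std::vector<std::pair<int, int> > &out) {
  int t_max = (L - 3) / (3 + min_loop);
  for (int T = t_max; T >= min_tracts - 1; --T) {
    Matcher m(s, L, min_loop, max_loop, min_tracts, true, T);
    if (m.cont(0, 0) && m.match_end == L) {
      out = m.loops;
      return true;
    }
  }
  return false;
}

} // namespace

// Scan one sequence (uppercase) on one strand.  Match spans are the
// leftmost non-overlapping greedy (PCRE-order) matches; each span is then
// tokenized with the tract-count-maximizing parse.  Coordinates are 0-based
// half-open on the scanned string.
// [[Rcpp::export(name = ".cpp_scan_pg4")]]
List cpp_scan_pg4(std::string seq, int min_loop, int max_loop,
                  int min_tracts) {
  const char *s = seq.c_str();
  int L = (int)seq.size();
  std::vector<int> starts, ends;
  std::vector<std::vector<std::string> > all_loops;
  Matcher engine(s, L, min_loop, max_loop, min_tracts, false, -1);
  int p = 0;
  while (p + 3 <= L) {
    if (!engine.stem_at(p)) {
      ++p;
      continue;
    }
    engine.loops.clear();
    engine.match_end = -1;
    if (engine.cont(p, 0)) {
      int e = engine.match_end;
      std::vector<std::pair<int, int> > toks;
      if (!tokenize_span(s + p, e - p, min_loop, max_loop, min_tracts, toks))
        stop("internal error: matched span failed to tokenize"); // LCOV_EXCL_LINE
      starts.push_back(p);
      ends.push_back(e);
      std::vector<std::string> lv;
      for (size_t i = 0; i < toks.size(); ++i)
        lv.push_back(seq.substr(p + toks[i].first, toks[i].second));
      all_loops.push_back(lv);
      p = e; // non-overlapping: resume after the match
    } else {
      ++p;
    }
  }
  int n = (int)starts.size();
  IntegerVector rs(n), re(n);
  List rl(n);
  for (int i = 0; i < n; ++i) {
    rs[i] = starts[i];
    re[i] = ends[i];
    rl[i] = wrap(all_loops[i]);
  }
  return List::create(_["start"] = rs, _["end"] = re, _["loops"] = rl);
}

// Anchored tokenization of a full motif string: the whole string must be
// consumed.  Returns the loop tokens or NULL when the string is not a motif.
// [[Rcpp::export(name = ".cpp_parse_pg4")]]
SEXP cpp_parse_pg4(std::string seq, int min_loop, int max_loop,
                   int min_tracts) {
  const char *s = seq.c_str();
  int L = (int)seq.size();
  std::vector<std::pair<int, int> > toks;
  if (L >= 3 && tokenize_span(s, L, min_loop, max_loop, min_tracts, toks)) {
    std::vector<std::string> lv;
    for (size_t i = 0; i < toks.size(); ++i)
      lv.push_back(seq.substr(toks[i].first, toks[i].second));
    return wrap(lv);
  }
  return R_NilValue;
}
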