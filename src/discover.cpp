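#include <Rcpp.h>
#include <string>
#include <vector>

// Exhaustive discriminative pattern search over 12-mer peptide sets.
//
// Patterns are strings over the residue alphabet plus '.', built by
// appending one symbol at a time (a residue letter or a wildcard; wildcards
// are never terminal). Each search node carries its match list: the (peptide,
// offset) positions where the pattern occurs in the query and the reference
// set. Appending a symbol filters the parent's list, so distinct-peptide
// support is monotone non-increasing and pruning on minimum support keeps
// the search exhaustive within the span bound.

using namespace Rcpp;

namespace {

struct MatchList {
  std::vector<int> pid;  // 0-based peptide index
  std::vector<int> off;  // 0-based start offset
};

struct Ctx {
  const IntegerMatrix& Mq;  // query peptides, residue codes 1..20
  const IntegerMatrix& Mr;  // reference peptides
  const NumericVector& wq;  // per-peptide abundance weight (query)
  const NumericVector& wr;
  double nq_tot, nr_tot;    // abundance totals in the configured units
  int min_support, min_fixed, max_span;
  double min_fold, max_p;
  std::string letters;      // code -> residue char
  std::vector<int> stamp_q, stamp_r;
  int token;
  // output columns
  std::vector<std::string> pat;
  std::vector<double> kq, kr, fold, pval;
  std::vector<int> fixed, span, uq, ur;
};

// Distinct-peptide count and abundance-weight sum of a match list.
void distinct_stats(const MatchList& ml, std::vector<int>& stamp, int token,
                    const NumericVector& w, int* n_distinct, double* wsum) {
  int n = 0;
  double s = 0.0;
  for (size_t i = 0; i < ml.pid.size(); ++i) {
    int p = ml.pid[i];
    if (stamp[p] != token) {
      stamp[p] = token;
      ++n;
      s += w[p];
    }
  }
  *n_distinct = n;
  *wsum = s;
}

void maybe_report(Ctx& c, const std::string& pattern, int nfixed,
                  const MatchList& q, const MatchList& r) {
  if (nfixed < c.min_fixed) return;
  int uq, ur;
  double kq, kr;
  ++c.token;
  distinct_stats(q, c.stamp_q, c.token, c.wq, &uq, &kq);
  ++c.token;
  distinct_stats(r, c.stamp_r, c.token, c.wr, &ur, &kr);
  double fold = (kq / c.nq_tot) / ((kr + 1.0) / c.nr_tot);
  if (fold < c.min_fold) return;
  // hypergeometric upper tail on distinct peptides:
  // N = all distinct peptides, K = all matching, n = query peptides,
  // k = matching in query; p = P(X >= k)
  double N = c.Mq.nrow() + c.Mr.nrow();
  double K = uq + ur;
  double p = R::phyper(uq - 1.0, K, N - K, (double)c.Mq.nrow(), 0, 0);
  if (!(p < c.max_p)) return;
  c.pat.push_back(pattern);
  c.kq.push_back(kq);
  c.kr.push_back(kr);
  c.fold.push_back(fold);
  c.pval.push_back(p);
  c.fixed.push_back(nfixed);
  c.span.push_back((int)pattern.size());
  c.uq.push_back(uq);
  c.ur.push_back(ur);
}

// Filter a parent match list into per-symbol child lists. buck[0] is the
// wildcard child (every entry whose window still fits); buck[1..20] require
// the next residue to equal that code.
void bucket(const MatchList& ml, const IntegerMatrix& M, int span,
            std::vector<MatchList>& buck) {
  for (auto& b : buck) {
    b.pid.clear();
    b.off.clear();
  }
  const int L = M.ncol();
  for (size_t i = 0; i < ml.pid.size(); ++i) {
    int p = ml.pid[i], o = ml.off[i];
    if (o + span >= L) continue;
    int code = M(p, o + span);
    buck[0].pid.push_back(p);
    buck[0].off.push_back(o);
    buck[code].pid.push_back(p);
    buck[code].off.push_back(o);
  }
}

int support(Ctx& c, const MatchList& q) {
  ++c.token;
  int n = 0;
  for (size_t i = 0; i < q.pid.size(); ++i) {
    int p = q.pid[i];
    if (c.stamp_q[p] != c.token) {
      c.stamp_q[p] = c.token;
      ++n;
    }
  }
  return n;
}

void expand(Ctx& c, const std::string& pattern, int nfixed,
            const MatchList& q, const MatchList& r) {
  int span = (int)pattern.size();
  if (pattern.back() != '.') maybe_report(c, pattern, nfixed, q, r);
  if (span >= c.max_span) return;
  std::vector<MatchList> bq(21), br(21);
  bucket(q, c.Mq, span, bq);
  bucket(r, c.Mr, span, br);
  // wildcard child: needs room for at least one further residue
  if (span + 1 < c.max_span && support(c, bq[0]) >= c.min_support)
    expand(c, pattern + '.', nfixed, bq[0], br[0]);
  for (int code = 1; code <= 20; ++code) {
    if (support(c, bq[code]) >= c.min_support)
      expand(c, pattern + c.letters[code - 1], nfixed + 1, bq[code],
             br[code]);
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_discover(IntegerMatrix Mq, NumericVector wq, double nq_tot,
                  IntegerMatrix Mr, NumericVector wr, double nr_tot,
                  int min_support, int min_fixed, int max_span,
                  double min_fold, double max_p, std::string letters) {
  Ctx c{Mq, Mr, wq, wr, nq_tot, nr_tot, min_support, min_fixed,
        max_span, min_fold, max_p, letters,
        std::vector<int>(Mq.nrow(), -1), std::vector<int>(Mr.nrow(), -1),
        0, {}, {}, {}, {}, {}, {}, {}, {}, {}};
  const int L = Mq.ncol();
  for (int code = 1; code <= 20; ++code) {
    MatchList q, r;
    for (int p = 0; p < Mq.nrow(); ++p)
      for (int o = 0; o < L; ++o)
        if (Mq(p, o) == code) {
          q.pid.push_back(p);
          q.off.push_back(o);
        }
    for (int p = 0; p < Mr.nrow(); ++p)
      for (int o = 0; o < Mr.ncol(); ++o)
        if (Mr(p, o) == code) {
          r.pid.push_back(p);
          r.off.push_back(o);
        }
    if (support(c, q) >= c.min_support)
      expand(c, std::string(1, letters[code - 1]), 1, q, r);
  }
  return List::create(
      _["pattern"] = c.pat, _["fixed_count"] = c.fixed, _["span"] = c.span,
      _["k_query"] = c.kq, _["k_ref"] = c.kr, _["fold"] = c.fold,
      _["p_value"] = c.pval, _["unique_query"] = c.uq,
      _["unique_ref"] = c.ur);
}
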