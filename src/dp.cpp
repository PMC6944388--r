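#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Tie-break in the traceback is fixed: diagonal > up (gap in b) > left
// (gap in a), so the reported alignment -- and hence the percent
// identity -- is deterministic.
static void nw_core(const std::string& a, const std::string& b,
                    double match, double mismatch, double gap,
                    double& score, std::string& ra, std::string& rb) {
  const int n = a.size(), m = b.size();
  std::vector<std::vector<double> > F(n + 1, std::vector<double>(m + 1, 0.0));
  for (int i = 1; i <= n; ++i) F[i][0] = i * gap;
  for (int j = 1; j <= m; ++j) F[0][j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      F[i][j] = std::max(F[i - 1][j - 1] + s,
                         std::max(F[i - 1][j] + gap, F[i][j - 1] + gap));
    }
  }
  score = F[n][m];
  ra.clear(); rb.clear();
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (F[i][j] == F[i - 1][j - 1] + s) {
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j; continue;
      }
    }
    if (i > 0 && F[i][j] == F[i - 1][j] + gap) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i; continue;
    }
    ra.push_back('-'); rb.push_back(b[j - 1]); --j;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
}

static double pid_from_alignment(const std::string& ra, const std::string& rb) {
  int ident = 0;
  for (size_t k = 0; k < ra.size(); ++k)
    if (ra[k] == rb[k] && ra[k] != '-') ++ident;
  return 100.0 * ident / (double)ra.size();
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  double score; std::string ra, rb;
  nw_core(a, b, match, mismatch, gap, score, ra, rb);
  return List::create(_["score"] = score,
                      _["aligned_a"] = ra,
                      _["aligned_b"] = rb,
                      _["percent_identity"] = pid_from_alignment(ra, rb));
}

// Percent identity for every unordered pair; diagonal is 100.
// [[Rcpp::export]]
NumericMatrix pid_matrix_cpp(CharacterVector seqs,
                             double match, double mismatch, double gap) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 100.0;
    for (int j = i + 1; j < n; ++j) {
      double score; std::string ra, rb;
      nw_core(s[i], s[j], match, mismatch, gap, score, ra, rb);
      const double p = pid_from_alignment(ra, rb);
      out(i, j) = p;
      out(j, i) = p;
    }
  }
  return out;
}

static bool can_pair(char x, char y) {
  return (x == 'A' && y == 'U') || (x == 'U' && y == 'A') ||
         (x == 'G' && y == 'C') || (x == 'C' && y == 'G') ||
         (x == 'G' && y == 'U') || (x == 'U' && y == 'G');
}

// Nussinov base-pair maximisation with a hairpin constraint: a pair
// (i, j) requires j - i - 1 >= min_loop.  Traceback tie-break is fixed
// and documented: prefer leaving i unpaired, then the smallest partner.
// [[Rcpp::export]]
std::string nussinov_cpp(std::string s, int min_loop) {
  const int n = s.size();
  std::string db(n, '.');
  if (n == 0) return db;
  std::vector<std::vector<int> > N(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      int best = N[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(s[i], s[k])) continue;
        const int inner = N[i + 1][k - 1];
        const int right = (k < j) ? N[k + 1][j] : 0;
        best = std::max(best, inner + right + 1);
      }
      N[i][j] = best;
    }
  }
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    const int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i - 1 < min_loop) continue;
    if (N[i][j] == N[i + 1][j]) {  // prefer i unpaired
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(s[i], s[k])) continue;
      const int inner = N[i + 1][k - 1];
      const int right = (k < j) ? N[k + 1][j] : 0;
      if (inner + right + 1 == N[i][j]) {  // smallest partner k
        db[i] = '('; db[k] = ')';
        stack.push_back(std::make_pair(i + 1, k - 1));
        if (k < j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return db;
}
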