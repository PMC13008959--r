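#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalties.
// Returns the optimal score and the traceback of one optimal alignment;
// ties are broken toward the smallest (end_i, end_j) cell and, within the
// traceback, diagonal > up > left, which yields the left-most optimal match.
// Coordinates in the result are 0-based half-open on the input strings.
// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b,
                     double match, double mismatch, double gap) {
  int n = a.size(), m = b.size();
  std::vector<std::vector<double> > H(n + 1, std::vector<double>(m + 1, 0.0));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double diag = H[i - 1][j - 1] + s;
      double up = H[i - 1][j] + gap;
      double left = H[i][j - 1] + gap;
      double h = diag;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0.0) h = 0.0;
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["found"] = false);
  }
  // traceback
  int i = bi, j = bj;
  int matches = 0, columns = 0;
  std::string aa, ab;
  while (i > 0 && j > 0 && H[i][j] > 0.0) {
    double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
    if (H[i][j] == H[i - 1][j - 1] + s) {
      aa.push_back(a[i - 1]); ab.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) matches++;
      --i; --j;
    } else if (H[i][j] == H[i - 1][j] + gap) {
      aa.push_back(a[i - 1]); ab.push_back('-');
      --i;
    } else {
      aa.push_back('-'); ab.push_back(b[j - 1]);
      --j;
    }
    columns++;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ab.begin(), ab.end());
  return List::create(
    _["score"] = best, _["found"] = true,
    _["a_start"] = i, _["a_end"] = bi,
    _["b_start"] = j, _["b_end"] = bj,
    _["n_columns"] = columns, _["n_matches"] = matches,
    _["aligned_a"] = aa, _["aligned_b"] = ab);
}

static double site_penalty_dp(const std::string &window, const std::string &site,
                              const NumericVector &weight,
                              double mismatch, double wobble, double gap) {
  int n = window.size(), m = site.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  prev[0] = 0.0;
  for (int j = 1; j <= m; ++j) prev[j] = prev[j - 1] + gap * weight[j - 1];
  for (int i = 1; i <= n; ++i) {
    cur[0] = prev[0] + gap * weight[0];
    for (int j = 1; j <= m; ++j) {
      char w = window[i - 1], s = site[j - 1];
      double sub;
      if (w == s) sub = 0.0;
      else if ((s == 'C' && w == 'T') || (s == 'A' && w == 'G')) sub = wobble;
      else sub = mismatch;
      double d = prev[j - 1] + sub * weight[j - 1];
      double up = prev[j] + gap * weight[j - 1];
      double left = cur[j - 1] + gap * weight[j - 1];
      if (up < d) d = up;
      if (left < d) d = left;
      cur[j] = d;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Penalty of every window of length site.size() along the target.
// [[Rcpp::export]]
NumericVector cpp_scan_penalties(std::string target, std::string site,
                                 NumericVector weight,
                                 double mismatch, double wobble, double gap) {
  int L = site.size();
  int n = target.size();
  if (n < L) stop("target shorter than site");
  NumericVector out(n - L + 1);
  for (int s = 0; s <= n - L; ++s) {
    out[s] = site_penalty_dp(target.substr(s, L), site, weight,
                             mismatch, wobble, gap);
  }
  return out;
}

// Global (Needleman-Wunsch) penalty-minimizing alignment of a target window
// against the ideal binding site (reverse complement of the miRNA), with
// position-dependent weights along the site: `weight[j]` multiplies every
// penalty attributed to site position j (seed-region doubling). Penalties:
// perfect pair 0, G:U wobble `wobble`, mismatch `mismatch`, gap `gap`.
// A wobble at site position j means the target base can still pair with the
// miRNA base through G:U: site 'C' (miRNA G) vs target 'T', or site 'A'
// (miRNA U) vs target 'G'.
// Tie-break: diagonal > up (gap in site) > left (gap in window), giving a
// deterministic left-most alignment.
// [[Rcpp::export]]
List cpp_site_penalty(std::string window, std::string site,
                      NumericVector weight,
                      double mismatch, double wobble, double gap) {
  int n = window.size(), m = site.size();
  if ((int) weight.size() != m) stop("weight length must equal site length");
  const double INF = 1e18;
  std::vector<std::vector<double> > D(n + 1, std::vector<double>(m + 1, INF));
  D[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) D[i][0] = D[i - 1][0] + gap * weight[0];
  for (int j = 1; j <= m; ++j) D[0][j] = D[0][j - 1] + gap * weight[j - 1];
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      char w = window[i - 1], s = site[j - 1];
      double sub;
      if (w == s) sub = 0.0;
      else if ((s == 'C' && w == 'T') || (s == 'A' && w == 'G')) sub = wobble;
      else sub = mismatch;
      double diag = D[i - 1][j - 1] + sub * weight[j - 1];
      double up   = D[i - 1][j] + gap * weight[j - 1 < 0 ? 0 : j - 1]; // gap in site axis: window base unpaired
      double left = D[i][j - 1] + gap * weight[j - 1];                 // site base unpaired
      double d = diag;
      if (up < d) d = up;
      if (left < d) d = left;
      D[i][j] = d;
    }
  }
  // traceback
  int i = n, j = m;
  std::string aw, as, mid;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      char w = window[i - 1], s = site[j - 1];
      double sub;
      if (w == s) sub = 0.0;
      else if ((s == 'C' && w == 'T') || (s == 'A' && w == 'G')) sub = wobble;
      else sub = mismatch;
      if (D[i][j] == D[i - 1][j - 1] + sub * weight[j - 1]) {
        aw.push_back(w); as.push_back(s);
        mid.push_back(sub == 0.0 ? '|' : (sub == wobble ? 'o' : ' '));
        --i; --j; continue;
      }
    }
    if (i > 0 && D[i][j] == D[i - 1][j] + gap * weight[(j > 0 ? j : 1) - 1]) {
      aw.push_back(window[i - 1]); as.push_back('-'); mid.push_back(' ');
      --i; continue;
    }
    aw.push_back('-'); as.push_back(site[j - 1]); mid.push_back(' ');
    --j;
  }
  std::reverse(aw.begin(), aw.end());
  std::reverse(as.begin(), as.end());
  std::reverse(mid.begin(), mid.end());
  return List::create(_["penalty"] = D[n][m],
                      _["aligned_window"] = aw,
                      _["aligned_site"] = as,
                      _["midline"] = mid);
}
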