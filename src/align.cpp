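#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstdlib>

using namespace Rcpp;

// Banded global alignment of each haplotype to the dominant haplotype with
// unit costs (mismatch 1, gap 1), projected onto the dominant's
// coordinates: output strings have one character per dominant position
// ('-' where the haplotype has a deletion; haplotype insertions are
// dropped). Haplotypes differ from the dominant by a handful of sequencing
// errors, so a narrow band suffices; the band is widened and the alignment
// retried if the optimum touches the band edge.

static const int BIG = 1 << 28;

static bool project_banded(const std::string& a, const std::string& dom,
                           int band, std::string& proj) {
  const int m = (int) a.size(), n = (int) dom.size();
  const int w = 2 * band + 1;
  // dp[i][j] stored at row i, offset j - (i + off0) + band, where the band
  // is centred on the diagonal j = i * n / max(m,1)
  std::vector<int> dp((size_t) (m + 1) * w, BIG);
  auto centre = [&](int i) { return m ? (int) ((long long) i * n / m) : 0; };
  auto at = [&](int i, int j) -> int& {
    return dp[(size_t) i * w + (j - centre(i) + band)];
  };
  auto inband = [&](int i, int j) {
    int d = j - centre(i) + band;
    return j >= 0 && j <= n && d >= 0 && d < w;
  };
  for (int j = 0; j <= std::min(n, band); ++j)
    if (inband(0, j)) at(0, j) = j;
  for (int i = 1; i <= m; ++i) {
    int c = centre(i);
    for (int j = std::max(0, c - band); j <= std::min(n, c + band); ++j) {
      int best = BIG;
      if (j > 0 && inband(i - 1, j - 1) && at(i - 1, j - 1) < BIG) {
        int v = at(i - 1, j - 1) + (a[i - 1] == dom[j - 1] ? 0 : 1);
        if (v < best) best = v;
      }
      if (inband(i - 1, j) && at(i - 1, j) < BIG) {
        int v = at(i - 1, j) + 1;
        if (v < best) best = v;
      }
      if (j > 0 && inband(i, j - 1) && at(i, j - 1) < BIG) {
        int v = at(i, j - 1) + 1;
        if (v < best) best = v;
      }
      if (j == 0 && best == BIG) best = i;
      at(i, j) = best;
    }
  }
  if (!inband(m, n) || at(m, n) >= BIG) return false;
  if (at(m, n) > band - 1) return false; // may have clipped the optimum
  proj.assign(n, '-');
  int i = m, j = n;
  while (i > 0 && j > 0) {
    int cur = at(i, j);
    if (inband(i - 1, j - 1) && at(i - 1, j - 1) < BIG &&
        cur == at(i - 1, j - 1) + (a[i - 1] == dom[j - 1] ? 0 : 1)) {
      proj[j - 1] = a[i - 1];
      --i; --j;
    } else if (inband(i - 1, j) && at(i - 1, j) < BIG &&
               cur == at(i - 1, j) + 1) {
      --i;
    } else {
      proj[j - 1] = '-';
      --j;
    }
  }
  return true;
}

// [[Rcpp::export(name = ".cm_project_onto")]]
CharacterVector cm_project_onto(CharacterVector haps, std::string dom) {
  const int n = (int) dom.size();
  CharacterVector out(haps.size());
  for (R_xlen_t h = 0; h < haps.size(); ++h) {
    std::string a = as<std::string>(haps[h]);
    if (a == dom) { out[h] = dom; continue; }
    int band = std::abs((int) a.size() - n) + 6;
    std::string proj;
    while (!project_banded(a, dom, band, proj)) {
      band *= 2;
      if (band > n + (int) a.size() + 2) { // degenerate: full-width band
        project_banded(a, dom, band, proj);
        break;
      }
    }
    if ((int) proj.size() != n) proj.assign(n, '-');
    out[h] = proj;
  }
  out.attr("names") = haps.attr("names");
  return out;
}

// Merge R1 inserts with reverse-complemented R2 inserts: try the expected
// overlap first, then nearby shifts, then a full descending scan; accept
// an overlap >= min_overlap with <= max_mismatch substitutions. Failing
// all, join with '+'.
// [[Rcpp::export(name = ".cm_merge_pairs")]]
CharacterVector cm_merge_pairs(CharacterVector ins1, CharacterVector ins2,
                               IntegerVector exp_ov, int min_overlap,
                               int max_mismatch) {
  R_xlen_t nn = ins1.size();
  CharacterVector out(nn);
  for (R_xlen_t i = 0; i < nn; ++i) {
    std::string a = as<std::string>(ins1[i]);
    std::string b = as<std::string>(ins2[i]);
    int na = (int) a.size(), nb = (int) b.size();
    int lim = std::min(na, nb);
    std::vector<int> cand;
    int e = exp_ov[i];
    int near[5] = {e, e - 1, e + 1, e - 2, e + 2};
    for (int v : near)
      if (v >= min_overlap && v <= lim) cand.push_back(v);
    for (int v = lim; v >= min_overlap; --v) {
      bool seen = false;
      for (int c : cand) if (c == v) { seen = true; break; }
      if (!seen) cand.push_back(v);
    }
    bool merged = false;
    for (int ov : cand) {
      int mm = 0;
      const char* pa = a.data() + (na - ov);
      for (int t = 0; t < ov && mm <= max_mismatch; ++t)
        if (pa[t] != b[t]) ++mm;
      if (mm <= max_mismatch) {
        out[i] = a + b.substr(ov);
        merged = true;
        break;
      }
    }
    if (!merged) out[i] = a + "+" + b;
  }
  return out;
}
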