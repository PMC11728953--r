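#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Space features for one test code across all decision points.
//
// dp_pat / obs_pat are 1-based patient indices over a shared roster;
// obs rows must be sorted by (patient, day). For each decision point the
// observations with day offset d = dp_day - obs_day in [0, window) are
// nearest-neighbour interpolated to daily values (ties to the more recent
// observation, no extrapolation) and each space of `space_width` days is
// summarised as log(mean of non-missing days); spaces with no day covered,
// or a non-positive mean, are NA.
// [[Rcpp::export]]
NumericMatrix space_features_code(IntegerVector dp_pat, IntegerVector dp_day,
                                  IntegerVector obs_pat, IntegerVector obs_day,
                                  NumericVector obs_val,
                                  int n_spaces, int space_width) {
  const int window = n_spaces * space_width;
  const int ndp = dp_pat.size();
  const int nobs = obs_pat.size();

  int npat = 0;
  for (int i = 0; i < ndp; ++i) npat = std::max(npat, dp_pat[i]);
  for (int i = 0; i < nobs; ++i) npat = std::max(npat, obs_pat[i]);

  // start offset of each patient's block in the sorted observation arrays
  std::vector<int> start(npat + 2, 0);
  for (int i = 0; i < nobs; ++i) start[obs_pat[i] + 1]++;
  for (int p = 1; p <= npat + 1; ++p) start[p] += start[p - 1];

  NumericMatrix out(ndp, n_spaces);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> ssum(n_spaces);
  std::vector<int> scnt(n_spaces);
  std::vector<int> off;
  std::vector<double> val;

  for (int i = 0; i < ndp; ++i) {
    const int p = dp_pat[i];
    const int day = dp_day[i];
    const int s = start[p], e = start[p + 1];
    if (s == e) continue;
    // obs_day ascending within the patient; offsets descend with obs_day
    off.clear(); val.clear();
    for (int j = e - 1; j >= s; --j) {
      const int d = day - obs_day[j];
      if (d < 0) continue;
      if (d >= window) break;
      off.push_back(d);
      val.push_back(obs_val[j]);
    }
    const int m = (int)off.size();
    if (m == 0) continue;
    std::fill(ssum.begin(), ssum.end(), 0.0);
    std::fill(scnt.begin(), scnt.end(), 0);
    int j = 0;
    for (int d = off[0]; d <= off[m - 1]; ++d) {
      // advance while the next (older) observation is strictly closer;
      // an exact tie keeps the more recent neighbour
      while (j + 1 < m && (off[j + 1] - d) < (d - off[j])) ++j;
      const int k = d / space_width;
      ssum[k] += val[j];
      scnt[k] += 1;
    }
    for (int k = 0; k < n_spaces; ++k) {
      if (scnt[k] == 0) continue;
      const double mean = ssum[k] / scnt[k];
      if (mean > 0) out(i, k) = std::log(mean);
    }
  }
  return out;
}
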