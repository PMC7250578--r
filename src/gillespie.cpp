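#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact continuous-time (Gillespie) simulation of the centrosome-class
// branching process. States: 0 = C2, 1 = C4, 2 = SC, 3 = C6. Cells of each
// class divide/die at exponential rates; division outcomes follow the fate
// tables of Model I/II. Uses R's RNG so set.seed() governs reproducibility.
//
// Event kind codes in the log:
//   1 bipolar-symmetric, 2 bipolar-asymmetric, 3 multipolar-survive,
//   4 multipolar-fatal, 5 cytokinesis-failure, 6 death
// [[Rcpp::export]]
List gillespie_core(IntegerVector init, List pars, bool model2,
                    NumericVector sample_times, int cap,
                    bool record_events, double max_events) {
  const double b2 = pars["b_C2"], b4 = pars["b_C4"], q = pars["q"],
               p = pars["p_bipolar"], r = pars["r"], fs = pars["fs"],
               d2 = pars["d_C2"], d4 = pars["d_C4"], d6 = pars["d_C6"],
               v = pars["v"], rS = pars["r_S"];
  long long n[4] = {init[0], init[1], init[2], init[3]};
  const int ns = sample_times.size();
  NumericMatrix out(ns, 4);
  double t = 0.0;
  int si = 0;
  double n_events = 0.0;
  bool extinct = false;

  // id pools per type (only maintained when recording events)
  std::vector<std::vector<int> > pool(4);
  int next_id = 0;
  if (record_events) {
    for (int k = 0; k < 4; ++k)
      for (long long i = 0; i < n[k]; ++i) pool[k].push_back(next_id++);
  }
  std::vector<double> ev_time;
  std::vector<int> ev_id, ev_type, ev_kind, ev_d1_id, ev_d1_type,
                   ev_d2_id, ev_d2_type;

  const double tmax = sample_times[ns - 1];

  auto draw_id = [&](int type) -> int {
    // uniform draw with O(1) swap-remove
    int m = (int) pool[type].size();
    int j = (int) (unif_rand() * m);
    if (j >= m) j = m - 1;
    int id = pool[type][j];
    pool[type][j] = pool[type][m - 1];
    pool[type].pop_back();
    return id;
  };

  while (t < tmax) {
    double rates[7] = {b2 * n[0], b4 * n[1], model2 ? b2 * n[2] : 0.0,
                       d2 * n[0], d4 * n[1], model2 ? d2 * n[2] : 0.0,
                       d6 * n[3]};
    double R = 0.0;
    for (int k = 0; k < 7; ++k) R += rates[k];
    if (R <= 0.0) { extinct = (n[0] + n[1] + n[2] + n[3] == 0); break; }
    t += exp_rand() / R;
    while (si < ns && sample_times[si] <= t) {
      for (int k = 0; k < 4; ++k) out(si, k) = (double) n[k];
      ++si;
    }
    if (t >= tmax) break;
    n_events += 1.0;
    if (n_events > max_events)
      stop("Event budget exceeded (%.0f events); raise `max_events` or lower the cap/horizon.", max_events);

    double u = unif_rand() * R, acc = 0.0;
    int ch = 6;
    for (int k = 0; k < 7; ++k) { acc += rates[k]; if (u < acc) { ch = k; break; } }

    int mother = -1, mtype = -1, kind = 0;
    int d1t = -1, d2t = -1;  // daughter types (-1 = none)
    if (ch == 0) {            // C2 division
      mtype = 0;
      if (unif_rand() < q) { kind = 1; d1t = 0; d2t = 0; n[0] += 1; }
      else {                  // cytokinesis failure -> one binucleate daughter
        kind = 5;
        n[0] -= 1;
        if (model2 && unif_rand() < v) { d1t = 2; n[2] += 1; }
        else { d1t = 1; n[1] += 1; }
      }
    } else if (ch == 1) {     // C4 division
      mtype = 1;
      if (unif_rand() < p) {  // bipolar
        if (unif_rand() < r) { kind = 1; d1t = 1; d2t = 1; n[1] += 1; }
        else { kind = 2; d1t = 0; d2t = 3; n[1] -= 1; n[0] += 1; n[3] += 1; }
      } else {                // multipolar: only a C4 daughter may survive
        n[1] -= 1;
        if (unif_rand() < fs) { kind = 3; d1t = 1; n[1] += 1; }
        else kind = 4;
      }
    } else if (ch == 2) {     // SC division
      mtype = 2;
      if (unif_rand() < rS) { kind = 1; d1t = 2; d2t = 2; n[2] += 1; }
      else { kind = 2; d1t = 0; d2t = 3; n[2] -= 1; n[0] += 1; n[3] += 1; }
    } else {                  // deaths
      mtype = ch - 3;         // 3,4,5,6 -> C2, C4, SC, C6
      kind = 6;
      n[mtype] -= 1;
    }

    if (record_events) {
      mother = draw_id(mtype);
      int i1 = -1, i2 = -1;
      if (d1t >= 0) { i1 = next_id++; pool[d1t].push_back(i1); }
      if (d2t >= 0) { i2 = next_id++; pool[d2t].push_back(i2); }
      ev_time.push_back(t); ev_id.push_back(mother); ev_type.push_back(mtype + 1);
      ev_kind.push_back(kind);
      ev_d1_id.push_back(i1); ev_d1_type.push_back(d1t + 1);
      ev_d2_id.push_back(i2); ev_d2_type.push_back(d2t + 1);
    }

    long long total = n[0] + n[1] + n[2] + n[3];
    if (total > cap) {
      // passaging: uniform subsample without replacement down to cap
      if (record_events) {
        std::vector<int> all_type;
        all_type.reserve(total);
        for (int k = 0; k < 4; ++k)
          for (size_t i = 0; i < pool[k].size(); ++i) all_type.push_back(k);
        // flatten ids alongside
        std::vector<int> all_id;
        all_id.reserve(total);
        for (int k = 0; k < 4; ++k)
          for (size_t i = 0; i < pool[k].size(); ++i) all_id.push_back(pool[k][i]);
        // partial Fisher-Yates for the first `cap` slots
        long long m = total;
        for (long long i = 0; i < cap; ++i) {
          long long j = i + (long long) (unif_rand() * (m - i));
          if (j >= m) j = m - 1;
          std::swap(all_type[i], all_type[j]);
          std::swap(all_id[i], all_id[j]);
        }
        for (int k = 0; k < 4; ++k) pool[k].clear();
        long long nn[4] = {0, 0, 0, 0};
        for (long long i = 0; i < cap; ++i) {
          pool[all_type[i]].push_back(all_id[i]);
          nn[all_type[i]] += 1;
        }
        for (int k = 0; k < 4; ++k) n[k] = nn[k];
      } else {
        // hypergeometric split of `cap` kept cells across the four classes
        long long remaining = total, keep = cap;
        for (int k = 0; k < 4; ++k) {
          long long kk;
          if (remaining == n[k]) kk = keep;
          else kk = (long long) R::rhyper((double) n[k],
                                          (double) (remaining - n[k]),
                                          (double) keep);
          remaining -= n[k];
          n[k] = kk;
          keep -= kk;
        }
      }
    }
  }
  while (si < ns) {
    for (int k = 0; k < 4; ++k) out(si, k) = (double) n[k];
    ++si;
  }
  extinct = (n[0] + n[1] + n[2] + n[3] == 0);

  List log;
  if (record_events) {
    log = List::create(
      _["time"] = wrap(ev_time), _["cell_id"] = wrap(ev_id),
      _["cell_type"] = wrap(ev_type), _["kind"] = wrap(ev_kind),
      _["daughter1_id"] = wrap(ev_d1_id), _["daughter1_type"] = wrap(ev_d1_type),
      _["daughter2_id"] = wrap(ev_d2_id), _["daughter2_type"] = wrap(ev_d2_type));
  }
  return List::create(_["counts"] = out, _["n_events"] = n_events,
                      _["extinct"] = extinct, _["events"] = log);
}
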