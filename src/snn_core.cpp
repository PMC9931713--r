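#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Discrete-time leaky integrate-and-fire simulation of one subject's spike
// train through the reservoir, optionally with additive STDP.
//
// Update order within a step t (1-based, t = 1..T):
//   1. u_i <- leak * u_i
//   2. propagation: every connection j->i whose pre neuron j fired at t-1
//      delivers its signed weight to u_i and counts as one transmission
//      event (weights as updated through step t-1)
//   3. input current: variable v's spike s_v(t) in {-1,0,+1} is added to the
//      membrane of v's input neuron
//   4. refractory neurons are clamped to u = 0 and cannot fire this step;
//      otherwise a neuron fires when u >= threshold, resets to 0 and becomes
//      refractory for `refractory` steps
//   5. STDP (if rate > 0): |w_ji| += rate when j fired at t-1 and i fires at
//      t; |w_ji| -= rate (floored at 0) when i fired at t-1 and j fires at t.
//      Signs are fixed at initialisation; STDP moves magnitudes only.
//
// conn_pre / conn_post are 0-based neuron indices; input_neurons maps each
// input variable (column of `spikes`) to a 0-based neuron index.
// [[Rcpp::export]]
List lif_run_cpp(int n_neurons,
                 IntegerVector conn_pre,
                 IntegerVector conn_post,
                 NumericVector conn_w,
                 IntegerVector input_neurons,
                 IntegerMatrix spikes,
                 double leak,
                 double threshold,
                 int refractory,
                 double stdp_rate,
                 bool record_raster,
                 bool record_events) {
  const int T = spikes.nrow();
  const int n_vars = spikes.ncol();
  const int nnz = conn_pre.size();

  // CSR over presynaptic neuron
  std::vector<int> deg(n_neurons, 0);
  for (int k = 0; k < nnz; ++k) deg[conn_pre[k]]++;
  std::vector<int> row_ptr(n_neurons + 1, 0);
  for (int i = 0; i < n_neurons; ++i) row_ptr[i + 1] = row_ptr[i] + deg[i];
  std::vector<int> csr_idx(nnz);
  {
    std::vector<int> fill(row_ptr.begin(), row_ptr.end() - 1);
    for (int k = 0; k < nnz; ++k) csr_idx[fill[conn_pre[k]]++] = k;
  }

  std::vector<double> wmag(nnz);
  std::vector<int> wsgn(nnz);
  for (int k = 0; k < nnz; ++k) {
    wmag[k] = std::abs(conn_w[k]);
    wsgn[k] = (conn_w[k] < 0.0) ? -1 : 1;
  }

  std::vector<double> u(n_neurons, 0.0);
  std::vector<int> refr(n_neurons, 0);
  std::vector<char> prev(n_neurons, 0), cur(n_neurons, 0);
  std::vector<int> fired_prev, fired_cur;
  fired_prev.reserve(n_neurons);
  fired_cur.reserve(n_neurons);
  std::vector<double> trans(nnz, 0.0);
  std::vector<int> ev_step, ev_pre, ev_post;

  IntegerMatrix raster(record_raster ? T : 0, record_raster ? n_neurons : 0);
  int* raster_ptr = record_raster ? INTEGER(raster) : nullptr;
  double n_firings = 0.0;

  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < n_neurons; ++i) u[i] *= leak;

    for (int j : fired_prev) {
      for (int p = row_ptr[j]; p < row_ptr[j + 1]; ++p) {
        const int k = csr_idx[p];
        u[conn_post[k]] += wsgn[k] * wmag[k];
        trans[k] += 1.0;
        if (record_events) {
          ev_step.push_back(t + 1);
          ev_pre.push_back(conn_pre[k] + 1);
          ev_post.push_back(conn_post[k] + 1);
        }
      }
    }

    for (int v = 0; v < n_vars; ++v) {
      const int s = spikes(t, v);
      if (s != 0) u[input_neurons[v]] += (double)s;
    }

    fired_cur.clear();
    for (int i = 0; i < n_neurons; ++i) {
      if (refr[i] > 0) {
        refr[i]--;
        u[i] = 0.0;
        cur[i] = 0;
      } else if (u[i] >= threshold) {
        cur[i] = 1;
        u[i] = 0.0;
        refr[i] = refractory;
        fired_cur.push_back(i);
        n_firings += 1.0;
      } else {
        cur[i] = 0;
      }
    }

    if (stdp_rate > 0.0) {
      for (int j : fired_prev) {
        for (int p = row_ptr[j]; p < row_ptr[j + 1]; ++p) {
          const int k = csr_idx[p];
          if (cur[conn_post[k]]) wmag[k] += stdp_rate;
        }
      }
      for (int j : fired_cur) {
        for (int p = row_ptr[j]; p < row_ptr[j + 1]; ++p) {
          const int k = csr_idx[p];
          if (prev[conn_post[k]])
            wmag[k] = std::max(0.0, wmag[k] - stdp_rate);
        }
      }
    }

    if (record_raster)
      for (int i : fired_cur) raster_ptr[(R_xlen_t)i * T + t] = 1;

    std::swap(prev, cur);
    std::swap(fired_prev, fired_cur);
  }

  NumericVector w_out(nnz);
  for (int k = 0; k < nnz; ++k) w_out[k] = wsgn[k] * wmag[k];
  NumericVector trans_out(trans.begin(), trans.end());

  List out = List::create(
      _["weights"] = w_out,
      _["trans_counts"] = trans_out,
      _["n_firings"] = n_firings);
  if (record_raster) out["raster"] = raster;
  if (record_events) {
    const int m = ev_step.size();
    IntegerMatrix ev(m, 3);
    for (int e = 0; e < m; ++e) {
      ev(e, 0) = ev_step[e];
      ev(e, 1) = ev_pre[e];
      ev(e, 2) = ev_post[e];
    }
    out["events"] = ev;
  }
  return out;
}

// Batched frozen-weight simulation + deSNN summarisation.
// spikes: integer array subjects x variables x time (flat, R array layout);
// returns a subjects x neurons matrix of deSNN weight vectors, computed
// online without materialising rasters.  Semantics identical to running
// lif_run_cpp per subject followed by desnn_weights_cpp on the raster.
// [[Rcpp::export]]
NumericMatrix lif_desnn_batch_cpp(int n_neurons,
                                  IntegerVector conn_pre,
                                  IntegerVector conn_post,
                                  NumericVector conn_w,
                                  IntegerVector input_neurons,
                                  IntegerVector spikes_arr,
                                  int n_subjects, int n_vars, int T,
                                  double leak, double threshold,
                                  int refractory,
                                  double mod, double drift) {
  const int nnz = conn_pre.size();
  std::vector<int> deg(n_neurons, 0);
  for (int k = 0; k < nnz; ++k) deg[conn_pre[k]]++;
  std::vector<int> row_ptr(n_neurons + 1, 0);
  for (int i = 0; i < n_neurons; ++i) row_ptr[i + 1] = row_ptr[i] + deg[i];
  std::vector<int> csr_idx(nnz);
  {
    std::vector<int> fill(row_ptr.begin(), row_ptr.end() - 1);
    for (int k = 0; k < nnz; ++k) csr_idx[fill[conn_pre[k]]++] = k;
  }
  const int* sp = INTEGER(spikes_arr);
  const double S = (double)n_subjects;
  (void)S;

  NumericMatrix out(n_subjects, n_neurons);
  std::vector<double> u(n_neurons), w(n_neurons);
  std::vector<int> refr(n_neurons);
  std::vector<char> prev(n_neurons), cur(n_neurons);
  std::vector<int> fired_prev, fired_cur, active;
  std::vector<char> seen(n_neurons);
  fired_prev.reserve(n_neurons);
  fired_cur.reserve(n_neurons);
  active.reserve(n_neurons);

  for (int s = 0; s < n_subjects; ++s) {
    std::fill(u.begin(), u.end(), 0.0);
    std::fill(w.begin(), w.end(), 0.0);
    std::fill(refr.begin(), refr.end(), 0);
    std::fill(prev.begin(), prev.end(), 0);
    std::fill(seen.begin(), seen.end(), 0);
    fired_prev.clear();
    active.clear();
    int rank = 0;

    for (int t = 0; t < T; ++t) {
      for (int i = 0; i < n_neurons; ++i) u[i] *= leak;
      for (int j : fired_prev)
        for (int p = row_ptr[j]; p < row_ptr[j + 1]; ++p) {
          const int k = csr_idx[p];
          u[conn_post[k]] += conn_w[k];
        }
      for (int v = 0; v < n_vars; ++v) {
        const int sv = sp[s + (R_xlen_t)n_subjects * (v + (R_xlen_t)n_vars * t)];
        if (sv != 0) u[input_neurons[v]] += (double)sv;
      }
      fired_cur.clear();
      for (int i = 0; i < n_neurons; ++i) {
        if (refr[i] > 0) {
          refr[i]--;
          u[i] = 0.0;
          cur[i] = 0;
        } else if (u[i] >= threshold) {
          cur[i] = 1;
          u[i] = 0.0;
          refr[i] = refractory;
          fired_cur.push_back(i);
        } else {
          cur[i] = 0;
        }
      }
      // drift for neurons already past their first spike
      for (int i : active)
        w[i] = std::max(0.0, w[i] + (cur[i] ? drift : -drift));
      // rank-order initialisation at first spike (fired_cur ascending => tie
      // break by neuron id)
      for (int i : fired_cur)
        if (!seen[i]) {
          seen[i] = 1;
          w[i] = std::pow(mod, (double)rank++);
          active.push_back(i);
        }
      std::swap(prev, cur);
      std::swap(fired_prev, fired_cur);
    }
    for (int i = 0; i < n_neurons; ++i) out(s, i) = w[i];
  }
  return out;
}

// deSNN readout weight vector from a binary raster (T x N).
// Rank-order initial weight mod^rank over first-spike times (ties by neuron
// index); afterwards, for every step past a neuron's first spike, the weight
// drifts up by `drift` when the neuron fires and down by `drift` (floored at
// 0) when it does not.  Neurons that never fire stay at 0.
// [[Rcpp::export]]
NumericVector desnn_weights_cpp(IntegerMatrix raster, double mod, double drift) {
  const int T = raster.nrow();
  const int N = raster.ncol();
  std::vector<int> first(N, -1);
  for (int i = 0; i < N; ++i)
    for (int t = 0; t < T; ++t)
      if (raster(t, i) != 0) { first[i] = t; break; }

  std::vector<int> fired;
  for (int i = 0; i < N; ++i)
    if (first[i] >= 0) fired.push_back(i);
  std::stable_sort(fired.begin(), fired.end(),
                   [&](int a, int b) { return first[a] < first[b]; });

  NumericVector w(N, 0.0);
  for (size_t r = 0; r < fired.size(); ++r) w[fired[r]] = std::pow(mod, (double)r);

  for (int i = 0; i < N; ++i) {
    if (first[i] < 0) continue;
    double wi = w[i];
    for (int t = first[i] + 1; t < T; ++t)
      wi = std::max(0.0, wi + (raster(t, i) != 0 ? drift : -drift));
    w[i] = wi;
  }
  return w;
}
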