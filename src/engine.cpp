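// Likelihood engine: Felsenstein pruning on unrooted binary trees with
// reversible 4-state models, discrete-gamma mixtures, per-pattern scaling,
// Brent branch-length optimization and NNI hill-climbing under an optional
// monophyly constraint.  Trees come in/out in ape's edge-matrix convention.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static const double SCALE_LO = 1e-120;

// ---- small xorshift RNG so searches are deterministic given an int seed ----
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t x = s;
    x ^= x << 13; x ^= x >> 7; x ^= x << 17;
    s = x; return x;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int upto(int n) { return (int)(unif() * n) % n; }
};

// ---- Brent 1-D maximizer on [a,b] ----
template <class F>
static double brent_max(F f, double a, double b, double tol, double* fbest) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double m = 0.5 * (a + b);
    double tol1 = tol + 1e-12 * std::fabs(x), tol2 = 2 * tol1;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
    double p = 0, q = 0, r = 0; bool useg = true;
    if (std::fabs(e) > tol1) {
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2 * (q - r);
      if (q > 0) p = -p; else q = -q;
      if (std::fabs(p) < std::fabs(0.5 * q * e) && p > q * (a - x) && p < q * (b - x)) {
        e = d; d = p / q; useg = false;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (m > x) ? tol1 : -tol1;
      }
    }
    if (useg) { e = (x < m) ? b - x : a - x; d = gold * e; }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu >= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu >= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fbest = fx;
  return x;
}

struct Engine {
  int ntip, nnode, nedge, npat, ncat, root;
  std::vector<std::array<int,3>> nbr, nbre; // neighbors / edge ids per node
  std::vector<int> deg;
  std::vector<int> ea, eb;                  // edge endpoints
  std::vector<double> elen;
  std::vector<double> tipc;                 // ntip*npat*4 tip conditionals
  std::vector<double> w;                    // pattern weights
  double U[16], Ui[16], lam[4], pi[4];
  std::vector<double> rates;
  // directed messages: d = 2e (ea->eb) or 2e+1 (eb->ea); value given state of
  // the RECEIVING node.  msg[d] has ncat*npat*4 entries, msgls[d] npat.
  std::vector<std::vector<double>> msg, msgls;
  double minlen, maxlen;

  int into(int e, int u) const { return (eb[e] == u) ? 2 * e : 2 * e + 1; }
  int other(int e, int u) const { return (ea[e] == u) ? eb[e] : ea[e]; }

  void transP(double t, double r, double* P) const {
    double E[4];
    for (int s = 0; s < 4; ++s) E[s] = std::exp(lam[s] * t * r);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        double v = 0;
        for (int s = 0; s < 4; ++s) v += U[i * 4 + s] * E[s] * Ui[s * 4 + j];
        P[i * 4 + j] = (v > 0) ? v : 0.0;
      }
  }

  // product of messages into u over all edges except eskip (-1 = none);
  // H: ncat*npat*4, Hls: npat.  Tips use their conditionals.
  void compH(int u, int eskip, double* H, double* Hls) const {
    int N = ncat * npat * 4;
    if (u < ntip) {
      for (int c = 0; c < ncat; ++c)
        std::copy(tipc.begin() + (size_t)u * npat * 4,
                  tipc.begin() + (size_t)(u + 1) * npat * 4,
                  H + (size_t)c * npat * 4);
      std::fill(Hls, Hls + npat, 0.0);
      return;
    }
    std::fill(H, H + N, 1.0);
    std::fill(Hls, Hls + npat, 0.0);
    for (int k = 0; k < deg[u]; ++k) {
      int e = nbre[u][k];
      if (e == eskip) continue;
      int d = into(e, u);
      const double* m = msg[d].data();
      for (int i = 0; i < N; ++i) H[i] *= m[i];
      const double* ls = msgls[d].data();
      for (int p = 0; p < npat; ++p) Hls[p] += ls[p];
    }
  }

  // message along e from x into y, from a given sender-side product H/Hls
  void applyEdge(int e, const double* H, const double* Hls,
                 double* out, double* outls) const {
    double P[16];
    for (int c = 0; c < ncat; ++c) {
      transP(elen[e], rates[c], P);
      const double* Hc = H + (size_t)c * npat * 4;
      double* oc = out + (size_t)c * npat * 4;
      for (int p = 0; p < npat; ++p) {
        const double* h = Hc + 4 * p;
        double* o = oc + 4 * p;
        for (int i = 0; i < 4; ++i)
          o[i] = P[i * 4] * h[0] + P[i * 4 + 1] * h[1] +
                 P[i * 4 + 2] * h[2] + P[i * 4 + 3] * h[3];
      }
    }
    // per-pattern rescale across categories
    for (int p = 0; p < npat; ++p) {
      double mx = 0;
      for (int c = 0; c < ncat; ++c) {
        const double* o = out + ((size_t)c * npat + p) * 4;
        for (int i = 0; i < 4; ++i) if (o[i] > mx) mx = o[i];
      }
      if (mx > 0 && mx < SCALE_LO) {
        double inv = 1.0 / mx;
        for (int c = 0; c < ncat; ++c) {
          double* o = out + ((size_t)c * npat + p) * 4;
          for (int i = 0; i < 4; ++i) o[i] *= inv;
        }
        outls[p] = Hls[p] + std::log(mx);
      } else {
        outls[p] = Hls[p];
      }
    }
  }

  void sendMsg(int e, int x, int y, std::vector<double>& bufH,
               std::vector<double>& bufLs) {
    compH(x, e, bufH.data(), bufLs.data());
    int d = into(e, y);
    applyEdge(e, bufH.data(), bufLs.data(), msg[d].data(), msgls[d].data());
  }

  // postorder list of (edge, child, parent) from root
  void dfsOrder(std::vector<std::array<int,3>>& post) const {
    post.clear();
    std::vector<std::array<int,3>> stack;
    std::vector<std::array<int,3>> pre;
    stack.push_back({-1, root, -1});
    while (!stack.empty()) {
      auto fr = stack.back(); stack.pop_back();
      int e = fr[0], u = fr[1], par = fr[2];
      if (e >= 0) pre.push_back({e, u, par});
      for (int k = 0; k < deg[u]; ++k) {
        int e2 = nbre[u][k];
        if (e2 == e) continue;
        stack.push_back({e2, other(e2, u), u});
      }
    }
    post.assign(pre.rbegin(), pre.rend());
  }

  void postMessages(std::vector<double>& bufH, std::vector<double>& bufLs) {
    std::vector<std::array<int,3>> post;
    dfsOrder(post);
    for (auto& f : post) sendMsg(f[0], f[1], f[2], bufH, bufLs);
  }

  void allMessages(std::vector<double>& bufH, std::vector<double>& bufLs) {
    std::vector<std::array<int,3>> post;
    dfsOrder(post);
    for (auto& f : post) sendMsg(f[0], f[1], f[2], bufH, bufLs);
    for (auto it = post.rbegin(); it != post.rend(); ++it)
      sendMsg((*it)[0], (*it)[2], (*it)[1], bufH, bufLs);
  }

  double rootLoglik(std::vector<double>& bufH, std::vector<double>& bufLs) const {
    compH(root, -1, bufH.data(), bufLs.data());
    double lnl = 0;
    for (int p = 0; p < npat; ++p) {
      double lik = 0;
      for (int c = 0; c < ncat; ++c) {
        const double* h = bufH.data() + ((size_t)c * npat + p) * 4;
        lik += pi[0] * h[0] + pi[1] * h[1] + pi[2] * h[2] + pi[3] * h[3];
      }
      lik /= ncat;
      lnl += w[p] * (std::log(lik) + bufLs[p]);
    }
    return lnl;
  }

  mutable std::vector<double> slbuf;

  // lnL as a function of one edge length, given the two side products
  double edgeLoglik(double t, const double* Hu, const double* lsu,
                    const double* Hv, const double* lsv) const {
    double P[16];
    if ((int)slbuf.size() < npat) slbuf.resize(npat);
    std::vector<double>& sl = slbuf;
    std::fill(sl.begin(), sl.begin() + npat, 0.0);
    for (int c = 0; c < ncat; ++c) {
      transP(t, rates[c], P);
      const double* Au = Hu + (size_t)c * npat * 4;
      const double* Av = Hv + (size_t)c * npat * 4;
      for (int p = 0; p < npat; ++p) {
        const double* a = Au + 4 * p;
        const double* b = Av + 4 * p;
        double s = 0;
        for (int i = 0; i < 4; ++i) {
          double pb = P[i * 4] * b[0] + P[i * 4 + 1] * b[1] +
                      P[i * 4 + 2] * b[2] + P[i * 4 + 3] * b[3];
          s += pi[i] * a[i] * pb;
        }
        sl[p] += s;
      }
    }
    double lnl = 0;
    for (int p = 0; p < npat; ++p) {
      double lik = sl[p] / ncat;
      if (lik <= 0) return -1e300;
      lnl += w[p] * (std::log(lik) + lsu[p] + lsv[p]);
    }
    return lnl;
  }

  // Brent within a window around the current length; widen to the full
  // bounds only when the optimum presses against the window edge.
  double optEdge(int e, const double* Hu, const double* lsu,
                 const double* Hv, const double* lsv) {
    double fbest;
    auto f = [&](double t) { return edgeLoglik(t, Hu, lsu, Hv, lsv); };
    double t0 = elen[e];
    double f0 = f(t0);
    double lo = std::max(minlen, t0 / 10.0);
    double hi = std::min(maxlen, t0 * 10.0 + 1e-4);
    double tol = 1e-7 + 3e-4 * t0;
    double t = brent_max(f, lo, hi, tol, &fbest);
    if ((t - lo < 2 * tol && lo > minlen * 1.01) ||
        (hi - t < 2 * tol && hi < maxlen * 0.99)) {
      t = brent_max(f, minlen, maxlen, 1e-7 + 3e-4 * t, &fbest);
    }
    if (fbest < f0) { t = t0; fbest = f0; } // never move downhill
    elen[e] = t;
    return fbest;
  }

  // Gauss-Seidel sweep: optimize every edge once, keeping messages exact.
  // Monotone in lnL because each edge sees fully up-to-date side products.
  void optRecurse(int e, int par, int v,
                  std::vector<double>& Hpar, std::vector<double>& lspar,
                  std::vector<double>& bufH, std::vector<double>& bufLs) {
    std::vector<double> Hv((size_t)ncat * npat * 4), lsv(npat);
    compH(v, e, Hv.data(), lsv.data());
    optEdge(e, Hpar.data(), lspar.data(), Hv.data(), lsv.data());
    if (v >= ntip) {
      // refresh the root-side message into v with the new length
      applyEdge(e, Hpar.data(), lspar.data(),
                msg[into(e, v)].data(), msgls[into(e, v)].data());
      for (int k = 0; k < deg[v]; ++k) {
        int e2 = nbre[v][k];
        if (e2 == e) continue;
        int c = other(e2, v);
        std::vector<double> Hvc((size_t)ncat * npat * 4), lsvc(npat);
        compH(v, e2, Hvc.data(), lsvc.data());
        optRecurse(e2, v, c, Hvc, lsvc, bufH, bufLs);
      }
    }
    // child-side message into par, with final lengths below
    sendMsg(e, v, par, bufH, bufLs);
  }

  double optimizeAll(double tol, int max_sweeps, std::vector<double>* trace) {
    std::vector<double> bufH((size_t)ncat * npat * 4), bufLs(npat);
    double prev = -1e300, cur = prev;
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      postMessages(bufH, bufLs);
      for (int k = 0; k < deg[root]; ++k) {
        int e = nbre[root][k];
        int c = other(e, root);
        std::vector<double> H((size_t)ncat * npat * 4), ls(npat);
        compH(root, e, H.data(), ls.data());
        optRecurse(e, root, c, H, ls, bufH, bufLs);
      }
      cur = rootLoglik(bufH, bufLs);
      if (trace) trace->push_back(cur);
      if (cur - prev < tol) break;
      prev = cur;
    }
    return cur;
  }

  double loglik() {
    std::vector<double> bufH((size_t)ncat * npat * 4), bufLs(npat);
    postMessages(bufH, bufLs);
    return rootLoglik(bufH, bufLs);
  }

  // ---- constraint bookkeeping: per directed edge, (#constraint tips, #tips)
  // on the SENDER side of the message direction.
  void sideCounts(const std::vector<int>& ctip,
                  std::vector<int>& cnt, std::vector<int>& sz) const {
    cnt.assign(2 * nedge, 0); sz.assign(2 * nedge, 0);
    std::vector<std::array<int,3>> post;
    dfsOrder(post);
    for (auto& f : post) {
      int e = f[0], ch = f[1], par = f[2];
      int d = into(e, par);
      if (ch < ntip) { cnt[d] = ctip[ch]; sz[d] = 1; }
      else {
        for (int k = 0; k < deg[ch]; ++k) {
          int e2 = nbre[ch][k];
          if (e2 == e) continue;
          int d2 = into(e2, ch);
          cnt[d] += cnt[d2]; sz[d] += sz[d2];
        }
      }
    }
    for (auto it = post.rbegin(); it != post.rend(); ++it) {
      int e = (*it)[0], ch = (*it)[1];
      int d = into(e, ch);
      cnt[d] = 0; sz[d] = 0;
      int par = (*it)[2];
      for (int k = 0; k < deg[par]; ++k) {
        int e2 = nbre[par][k];
        if (e2 == e) continue;
        int d2 = into(e2, par);
        cnt[d] += cnt[d2]; sz[d] += sz[d2];
      }
      if (par < ntip) { cnt[d] = ctip[par]; sz[d] = 1; } // cannot happen: par internal
    }
  }

  static bool realizes(int c, int s, int K, int ntip_) {
    return (c == K && s == K) || (c == 0 && (ntip_ - s) == K);
  }

  bool satisfied(const std::vector<int>& ctip) const {
    int K = 0;
    for (int v : ctip) K += v;
    if (K == 0 || K == ntip) return true;
    std::vector<int> cnt, sz;
    sideCounts(ctip, cnt, sz);
    for (int e = 0; e < nedge; ++e)
      if (realizes(cnt[2 * e + 1], sz[2 * e + 1], K, ntip)) return true;
    // 2e+1 is eb->ea, sender side eb; checking one orientation suffices
    for (int e = 0; e < nedge; ++e)
      if (realizes(cnt[2 * e], sz[2 * e], K, ntip)) return true;
    return false;
  }

  // swap neighbor a of node u with neighbor b of node v (NNI across edge u-v)
  void swapNbr(int u, int a, int v, int b) {
    int ku = -1, kv = -1;
    for (int k = 0; k < deg[u]; ++k) if (nbr[u][k] == a) ku = k;
    for (int k = 0; k < deg[v]; ++k) if (nbr[v][k] == b) kv = k;
    int eu = nbre[u][ku], ev = nbre[v][kv];
    nbr[u][ku] = b; nbre[u][ku] = ev;
    nbr[v][kv] = a; nbre[v][kv] = eu;
    // re-point edge endpoints
    if (ea[eu] == u) ea[eu] = v; else eb[eu] = v;
    if (ea[ev] == v) ea[ev] = u; else eb[ev] = u;
    // fix neighbor entries of a and b
    for (int k = 0; k < deg[a]; ++k) if (nbre[a][k] == eu && nbr[a][k] == u) nbr[a][k] = v;
    for (int k = 0; k < deg[b]; ++k) if (nbre[b][k] == ev && nbr[b][k] == v) nbr[b][k] = u;
  }
};

static Engine build_engine(int ntip, const IntegerMatrix& edge,
                           const NumericVector& elen,
                           const IntegerMatrix& tippat,
                           const NumericVector& w,
                           const NumericMatrix& U, const NumericMatrix& Ui,
                           const NumericVector& lam, const NumericVector& pi,
                           const NumericVector& rates,
                           double minlen, double maxlen) {
  Engine E;
  E.ntip = ntip;
  E.nedge = edge.nrow();
  int mx = 0;
  for (int i = 0; i < E.nedge; ++i) {
    mx = std::max(mx, edge(i, 0));
    mx = std::max(mx, edge(i, 1));
  }
  E.nnode = mx;
  E.npat = tippat.ncol();
  E.ncat = rates.size();
  E.minlen = minlen; E.maxlen = maxlen;
  E.nbr.assign(E.nnode, {{-1,-1,-1}});
  E.nbre.assign(E.nnode, {{-1,-1,-1}});
  E.deg.assign(E.nnode, 0);
  E.ea.resize(E.nedge); E.eb.resize(E.nedge);
  E.elen.assign(elen.begin(), elen.end());
  for (int i = 0; i < E.nedge; ++i) {
    int a = edge(i, 0) - 1, b = edge(i, 1) - 1;
    E.ea[i] = a; E.eb[i] = b;
    if (E.deg[a] >= 3 || E.deg[b] >= 3)
      stop("tree is not unrooted-binary (node degree > 3)");
    E.nbr[a][E.deg[a]] = b; E.nbre[a][E.deg[a]] = i; E.deg[a]++;
    E.nbr[b][E.deg[b]] = a; E.nbre[b][E.deg[b]] = i; E.deg[b]++;
  }
  E.root = -1;
  for (int u = ntip; u < E.nnode; ++u)
    if (E.deg[u] == 3) { E.root = u; break; }
  if (E.root < 0) stop("no trifurcating internal node; pass an unrooted tree");
  // tip conditionals from IUPAC bitmasks (A=1,C=2,G=4,T=8)
  E.tipc.assign((size_t)ntip * E.npat * 4, 0.0);
  for (int u = 0; u < ntip; ++u)
    for (int p = 0; p < E.npat; ++p) {
      int m = tippat(u, p);
      for (int s = 0; s < 4; ++s)
        if (m & (1 << s)) E.tipc[((size_t)u * E.npat + p) * 4 + s] = 1.0;
    }
  E.w.assign(w.begin(), w.end());
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      E.U[i * 4 + j] = U(i, j);
      E.Ui[i * 4 + j] = Ui(i, j);
    }
  for (int s = 0; s < 4; ++s) { E.lam[s] = lam[s]; E.pi[s] = pi[s]; }
  E.rates.assign(rates.begin(), rates.end());
  int nmsg = std::max(1, 2 * E.nedge);
  E.msg.assign(nmsg, std::vector<double>((size_t)E.ncat * E.npat * 4, 0.0));
  E.msgls.assign(nmsg, std::vector<double>(E.npat, 0.0));
  return E;
}

// rebuild an ape edge matrix (cladewise, root = ntip+1)
static List export_tree(Engine& E) {
  std::vector<int> newid(E.nnode, -1);
  int nextInternal = E.ntip + 1; // 1-based
  for (int u = 0; u < E.ntip; ++u) newid[u] = u + 1;
  newid[E.root] = nextInternal++;
  IntegerMatrix edge(E.nedge, 2);
  NumericVector elen(E.nedge);
  int row = 0;
  std::vector<std::array<int,3>> stack; // edge, child, parent
  for (int k = E.deg[E.root] - 1; k >= 0; --k) {
    int e = E.nbre[E.root][k];
    stack.push_back({e, E.other(e, E.root), E.root});
  }
  while (!stack.empty()) {
    auto f = stack.back(); stack.pop_back();
    int e = f[0], u = f[1], par = f[2];
    if (newid[u] < 0) newid[u] = nextInternal++;
    edge(row, 0) = newid[par];
    edge(row, 1) = newid[u];
    elen[row] = E.elen[e];
    ++row;
    for (int k = E.deg[u] - 1; k >= 0; --k) {
      int e2 = E.nbre[u][k];
      if (e2 == e) continue;
      stack.push_back({e2, E.other(e2, u), u});
    }
  }
  return List::create(_["edge"] = edge, _["edge.length"] = elen,
                      _["Nnode"] = E.nnode - E.ntip);
}

// [[Rcpp::export]]
double eng_loglik(int ntip, IntegerMatrix edge, NumericVector elen,
                  IntegerMatrix tippat, NumericVector w,
                  NumericMatrix U, NumericMatrix Ui, NumericVector lam,
                  NumericVector pi, NumericVector rates) {
  Engine E = build_engine(ntip, edge, elen, tippat, w, U, Ui, lam, pi, rates,
                          1e-8, 10.0);
  return E.loglik();
}

// [[Rcpp::export]]
List eng_optim(int ntip, IntegerMatrix edge, NumericVector elen,
               IntegerMatrix tippat, NumericVector w,
               NumericMatrix U, NumericMatrix Ui, NumericVector lam,
               NumericVector pi, NumericVector rates,
               double tol, int max_sweeps, double min_len, double max_len) {
  Engine E = build_engine(ntip, edge, elen, tippat, w, U, Ui, lam, pi, rates,
                          min_len, max_len);
  std::vector<double> trace;
  double lnl = E.optimizeAll(tol, max_sweeps, &trace);
  return List::create(_["edge.length"] = NumericVector(E.elen.begin(), E.elen.end()),
                      _["loglik"] = lnl,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// [[Rcpp::export]]
bool eng_satisfies(int ntip, IntegerMatrix edge, IntegerVector constraint) {
  NumericVector el(edge.nrow(), 0.1);
  IntegerMatrix tp(ntip, 1);
  std::fill(tp.begin(), tp.end(), 15);
  NumericVector w1 = NumericVector::create(1.0);
  NumericMatrix I4(4, 4);
  for (int i = 0; i < 4; ++i) I4(i, i) = 1.0;
  NumericVector lam(4), pi(4, 0.25), r1 = NumericVector::create(1.0);
  Engine E = build_engine(ntip, edge, el, tp, w1, I4, I4, lam, pi, r1,
                          1e-8, 10.0);
  std::vector<int> ctip(constraint.begin(), constraint.end());
  return E.satisfied(ctip);
}

struct Cand { int e, u, v, a, b; double t, lnl; };

// One NNI hill-climbing search from the given starting tree.
// constraint: length-ntip 0/1 (empty = unconstrained); n_perturb random
// constraint-respecting NNI moves are applied first (search replicates >1).
// [[Rcpp::export]]
List eng_search(int ntip, IntegerMatrix edge, NumericVector elen,
                IntegerMatrix tippat, NumericVector w,
                NumericMatrix U, NumericMatrix Ui, NumericVector lam,
                NumericVector pi, NumericVector rates,
                IntegerVector constraint, int n_perturb, int seed,
                int max_rounds, double tol_final, int final_sweeps,
                double min_len, double max_len) {
  Engine E = build_engine(ntip, edge, elen, tippat, w, U, Ui, lam, pi, rates,
                          min_len, max_len);
  bool hasC = constraint.size() > 0;
  std::vector<int> ctip;
  int K = 0;
  if (hasC) {
    ctip.assign(constraint.begin(), constraint.end());
    for (int v : ctip) K += v;
    if (K == 0 || K == ntip) hasC = false;
    else if (!E.satisfied(ctip))
      stop("starting tree does not satisfy the monophyly constraint");
  }
  XRng rng((uint64_t)seed * 2654435761ULL + 1ULL);

  // collect internal edges
  auto internalEdges = [&]() {
    std::vector<int> ie;
    for (int e = 0; e < E.nedge; ++e)
      if (E.ea[e] >= ntip && E.eb[e] >= ntip) ie.push_back(e);
    return ie;
  };

  if (n_perturb > 0) {
    std::vector<int> cnt, sz;
    for (int it = 0, done = 0; it < 50 * n_perturb && done < n_perturb; ++it) {
      std::vector<int> ie = internalEdges();
      if (ie.empty()) break;
      int e = ie[rng.upto((int)ie.size())];
      int u = E.ea[e], v = E.eb[e];
      std::array<int,2> pu, cv; int np = 0, nc = 0;
      for (int k = 0; k < E.deg[u]; ++k) if (E.nbr[u][k] != v) pu[np++] = E.nbr[u][k];
      for (int k = 0; k < E.deg[v]; ++k) if (E.nbr[v][k] != u) cv[nc++] = E.nbr[v][k];
      int a = pu[rng.upto(2)], b = cv[rng.upto(2)];
      if (hasC) {
        E.sideCounts(ctip, cnt, sz);
        // does edge e realize the constraint?
        bool eReal = Engine::realizes(cnt[2 * e], sz[2 * e], K, ntip) ||
                     Engine::realizes(cnt[2 * e + 1], sz[2 * e + 1], K, ntip);
        if (eReal) {
          // after swapping a<->b the u-side becomes {remaining u-nbr} + {b}
          int cU = 0, sU = 0;
          for (int k = 0; k < E.deg[u]; ++k) {
            int nb = E.nbr[u][k];
            if (nb == v || nb == a) continue;
            int d = E.into(E.nbre[u][k], u);
            cU += cnt[d]; sU += sz[d];
          }
          for (int k = 0; k < E.deg[v]; ++k) {
            if (E.nbr[v][k] != b) continue;
            int d = E.into(E.nbre[v][k], v);
            cU += cnt[d]; sU += sz[d];
          }
          if (!Engine::realizes(cU, sU, K, ntip)) continue;
        }
      }
      E.swapNbr(u, a, v, b);
      ++done;
    }
  }

  E.optimizeAll(0.05, 3, nullptr);
  std::vector<double> bufH((size_t)E.ncat * E.npat * 4), bufLs(E.npat);
  double cur = E.loglik();

  std::vector<int> cnt, sz;
  for (int round = 0; round < max_rounds; ++round) {
    E.allMessages(bufH, bufLs);
    cur = E.rootLoglik(bufH, bufLs);
    if (hasC) E.sideCounts(ctip, cnt, sz);
    std::vector<Cand> cands;
    std::vector<double> Hu((size_t)E.ncat * E.npat * 4), lsu(E.npat),
                        Hv((size_t)E.ncat * E.npat * 4), lsv(E.npat);
    for (int e : internalEdges()) {
      int u = E.ea[e], v = E.eb[e];
      int pu[2], cv[2], np = 0, nc = 0;
      int epu[2], ecv[2];
      for (int k = 0; k < E.deg[u]; ++k) {
        if (E.nbre[u][k] == e) continue;
        pu[np] = E.nbr[u][k]; epu[np] = E.nbre[u][k]; ++np;
      }
      for (int k = 0; k < E.deg[v]; ++k) {
        if (E.nbre[v][k] == e) continue;
        cv[nc] = E.nbr[v][k]; ecv[nc] = E.nbre[v][k]; ++nc;
      }
      bool eReal = hasC &&
        (Engine::realizes(cnt[2 * e], sz[2 * e], K, ntip) ||
         Engine::realizes(cnt[2 * e + 1], sz[2 * e + 1], K, ntip));
      for (int k = 0; k < 2; ++k) {
        // swap pu[1] with cv[k]: new u-side = {pu[0], cv[k]}
        if (hasC && eReal) {
          int cU = cnt[E.into(epu[0], u)] + cnt[E.into(ecv[k], v)];
          int sU = sz[E.into(epu[0], u)] + sz[E.into(ecv[k], v)];
          if (!Engine::realizes(cU, sU, K, ntip)) continue;
        }
        const double* m1 = E.msg[E.into(epu[0], u)].data();
        const double* m2 = E.msg[E.into(ecv[k], v)].data();
        const double* m3 = E.msg[E.into(epu[1], u)].data();
        const double* m4 = E.msg[E.into(ecv[1 - k], v)].data();
        const double* l1 = E.msgls[E.into(epu[0], u)].data();
        const double* l2 = E.msgls[E.into(ecv[k], v)].data();
        const double* l3 = E.msgls[E.into(epu[1], u)].data();
        const double* l4 = E.msgls[E.into(ecv[1 - k], v)].data();
        size_t N = (size_t)E.ncat * E.npat * 4;
        for (size_t i = 0; i < N; ++i) { Hu[i] = m1[i] * m2[i]; Hv[i] = m3[i] * m4[i]; }
        for (int p = 0; p < E.npat; ++p) { lsu[p] = l1[p] + l2[p]; lsv[p] = l3[p] + l4[p]; }
        double fbest;
        auto f = [&](double t) {
          return E.edgeLoglik(t, Hu.data(), lsu.data(), Hv.data(), lsv.data());
        };
        double tb = brent_max(f, min_len, max_len, 1e-4, &fbest);
        if (fbest > cur + 1e-8)
          cands.push_back({e, u, v, pu[1], cv[k], tb, fbest});
      }
    }
    if (cands.empty()) break;
    std::sort(cands.begin(), cands.end(),
              [](const Cand& a, const Cand& b) { return a.lnl > b.lnl; });
    // snapshot for possible revert
    Engine snap = E;
    std::vector<char> used(E.nnode, 0);
    int applied = 0;
    for (auto& c : cands) {
      if (used[c.u] || used[c.v] || used[c.a] || used[c.b]) continue;
      E.swapNbr(c.u, c.a, c.v, c.b);
      E.elen[c.e] = c.t;
      used[c.u] = used[c.v] = used[c.a] = used[c.b] = 1;
      ++applied;
    }
    double newl = E.optimizeAll(0.05, 2, nullptr);
    if (newl < cur + 1e-9 && applied > 1) {
      // simultaneous application overshot: fall back to the single best move
      E = snap;
      Cand c = cands.front();
      E.swapNbr(c.u, c.a, c.v, c.b);
      E.elen[c.e] = c.t;
      newl = E.optimizeAll(0.05, 2, nullptr);
    }
    if (newl < cur + 1e-9) { E = snap; break; }
    cur = newl;
  }
  cur = E.optimizeAll(tol_final, final_sweeps, nullptr);
  if (hasC && !E.satisfied(ctip)) stop("internal error: constraint violated");
  List tr = export_tree(E);
  tr["loglik"] = cur;
  return tr;
}
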