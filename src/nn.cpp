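// Ontology-structured convolutional classifier.
//
// Layout per forward pass: trigram indices -> learned embedding (padding
// index 0 is a frozen zero row) -> 1D valid convolution (nf filters, kernel
// k, ReLU) -> temporal max-pool (window pw, stride ps) -> flatten ->
// optional concatenation with the network-embedding vector -> dense ReLU
// layer (dunits) with dropout -> one small sigmoid subnet per selected
// ontology term (shared-input or cascade wiring) -> recursive max-merge
// over the selected-descendant closure of each term.
//
// Because the padding row of the embedding is identically zero, convolution
// windows that only cover padding equal relu(bias); the convolution is
// therefore evaluated only over the windows that touch real sequence, which
// keeps desk-scale training cheap without changing any output.
//
// Everything is single precision; gradients flow through the max-merge and
// the max-pool via their argmax. Optimiser: RMSprop on mean multi-output
// binary cross-entropy.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct ClassLayer {
  // units == 1: w2 has length idim, W1/b1 unused.
  // units  > 1: hidden ReLU layer W1 (u x idim) + output neuron w2 (u).
  fmat W1; fvec b1; fvec w2; float b2;
  fmat vW1; fvec vb1; fvec vw2; float vb2;   // rmsprop accumulators
  fmat gW1; fvec gb1; fvec gw2; float gb2;   // gradient accumulators
};

struct Net {
  // shape
  int vocab, edim, L, nf, k, pw, ps, units;
  int Lc, npool, flat, ndim, fdim, dunits, T;
  bool use_net, use_merge, cascade;
  float dropout;
  // wiring (0-based term indices)
  std::vector<uvec> closure;    // selected-descendant closure per term (self incl)
  std::vector<uvec> parents;    // induced direct parents per term (cascade)
  uvec topo_pf;                 // parents-before-children order
  // parameters
  fmat Et;        // edim x (vocab+1), column v = embedding of trigram v
  fmat Wc;        // nf x (k*edim)
  fvec bc;
  fmat Wd;        // dunits x fdim
  fvec bd;
  std::vector<ClassLayer> cls;
  // rmsprop state
  fmat vEt, vWc, vWd; fvec vbc, vbd;
  // gradient accumulators
  fmat gEt, gWc, gWd; fvec gbc, gbd;
  // workspaces
  fmat col, dcol, conv, dconv;
  std::mt19937 rng;

  int idim(int t) const {
    return dunits + (cascade ? (int)parents[t].n_elem : 0);
  }
};

static float urand(std::mt19937& rng, float lo, float hi) {
  std::uniform_real_distribution<float> d(lo, hi);
  return d(rng);
}

static void glorot(fmat& m, int fan_in, int fan_out, std::mt19937& rng) {
  float lim = std::sqrt(6.0f / (float)(fan_in + fan_out));
  for (uword i = 0; i < m.n_elem; ++i) m(i) = urand(rng, -lim, lim);
}
static void glorot(fvec& v, int fan_in, int fan_out, std::mt19937& rng) {
  float lim = std::sqrt(6.0f / (float)(fan_in + fan_out));
  for (uword i = 0; i < v.n_elem; ++i) v(i) = urand(rng, -lim, lim);
}

static std::vector<uvec> as_uvec_list(Rcpp::List l) {
  std::vector<uvec> out(l.size());
  for (int i = 0; i < l.size(); ++i) {
    Rcpp::IntegerVector v = l[i];
    uvec u(v.size());
    for (int j = 0; j < v.size(); ++j) u(j) = (uword)(v[j] - 1); // 1- -> 0-based
    out[i] = u;
  }
  return out;
}

// [[Rcpp::export(name = ".net_new")]]
SEXP net_new(Rcpp::List spec, Rcpp::List wiring, int seed) {
  Net* net = new Net();
  net->vocab = spec["vocab_size"];        // trigram count, excl. padding
  net->edim  = spec["embedding_dim"];
  net->L     = spec["seq_positions"];
  net->nf    = spec["conv_filters"];
  net->k     = spec["conv_kernel"];
  net->pw    = spec["pool_window"];
  net->ps    = spec["pool_stride"];
  net->ndim  = spec["net_dim"];
  net->dunits = spec["dense_units"];
  net->units = spec["class_layer_units"];
  net->use_net  = spec["use_net"];
  net->use_merge = spec["use_merge"];
  net->cascade  = spec["cascade"];
  net->dropout  = (float)Rcpp::as<double>(spec["dropout_rate"]);

  net->Lc = net->L - net->k + 1;
  if (net->Lc <= 0) Rcpp::stop("non-positive convolution output length");
  net->npool = (net->Lc - net->pw) / net->ps + 1;
  if (net->npool <= 0) Rcpp::stop("non-positive pooled length");
  net->flat = net->npool * net->nf;
  net->fdim = net->flat + (net->use_net ? net->ndim : 0);

  net->closure = as_uvec_list(wiring["closure"]);
  net->parents = as_uvec_list(wiring["parents"]);
  Rcpp::IntegerVector topo = wiring["topo_pf"];
  net->topo_pf.set_size(topo.size());
  for (int i = 0; i < topo.size(); ++i) net->topo_pf(i) = (uword)(topo[i] - 1);
  net->T = (int)net->closure.size();
  if (net->T <= 0) Rcpp::stop("empty term set");

  net->rng.seed((unsigned)seed);

  // embedding: small uniform, padding column frozen at zero
  net->Et.set_size(net->edim, net->vocab + 1);
  for (uword i = 0; i < net->Et.n_elem; ++i) net->Et(i) = urand(net->rng, -0.05f, 0.05f);
  net->Et.col(0).zeros();

  net->Wc.set_size(net->nf, net->k * net->edim);
  glorot(net->Wc, net->k * net->edim, net->k * net->nf, net->rng);
  net->bc.zeros(net->nf);
  net->Wd.set_size(net->dunits, net->fdim);
  glorot(net->Wd, net->fdim, net->dunits, net->rng);
  net->bd.zeros(net->dunits);

  net->cls.resize(net->T);
  for (int t = 0; t < net->T; ++t) {
    ClassLayer& c = net->cls[t];
    int idim = net->idim(t);
    if (net->units > 1) {
      c.W1.set_size(net->units, idim); glorot(c.W1, idim, net->units, net->rng);
      c.b1.zeros(net->units);
      c.w2.set_size(net->units); glorot(c.w2, net->units, 1, net->rng);
    } else {
      c.w2.set_size(idim); glorot(c.w2, idim, 1, net->rng);
    }
    c.b2 = 0.0f;
  }

  net->col.set_size(net->k * net->edim, net->Lc);
  net->dcol.set_size(net->k * net->edim, net->Lc);
  net->conv.set_size(net->nf, net->Lc);
  net->dconv.set_size(net->nf, net->Lc);

  Rcpp::XPtr<Net> ptr(net, true);
  return ptr;
}

struct FwdState {
  int Jc;
  fvec x, h_pre, h, hdrop, dropmask;
  fvec a, out, z;
  std::vector<fvec> mid_pre, mid;        // per-term hidden (units > 1)
  ivec pool_arg;                         // npool*nf, conv position or -1
  fvec bact;
  ivec merge_arg;
};

// forward one sample; idx is the row of the index matrix (length L)
static void forward_one(Net* net, const int* idx, const double* nvec,
                        bool train, FwdState& st) {
  int L = net->L, k = net->k, edim = net->edim, nf = net->nf;
  int Jnz = 0;
  for (int i = 0; i < L; ++i) if (idx[i] > 0) Jnz = i + 1;
  int Jc = std::min(net->Lc, Jnz);
  st.Jc = Jc;

  // im2col over the windows that touch real sequence
  for (int j = 0; j < Jc; ++j) {
    float* dst = net->col.colptr(j);
    for (int p = 0; p < k; ++p) {
      int pos = j + p;
      int v = (pos < L) ? idx[pos] : 0;
      if (v < 0 || v > net->vocab) Rcpp::stop("trigram index out of range");
      std::memcpy(dst + (size_t)p * edim, net->Et.colptr(v),
                  sizeof(float) * edim);
    }
  }
  if (Jc > 0) {
    net->conv.head_cols(Jc) = net->Wc * net->col.head_cols(Jc);
    net->conv.head_cols(Jc).each_col() += net->bc;
  }
  st.bact = net->bc;
  st.bact.transform([](float v) { return v > 0.0f ? v : 0.0f; });

  // temporal max-pool with argmax bookkeeping (-1 = padding-only zone)
  st.pool_arg.set_size(net->npool * nf);
  st.x.set_size(net->fdim);
  for (int w = 0; w < net->npool; ++w) {
    int t0 = w * net->ps, t1 = t0 + net->pw;
    int tc = std::min(t1, Jc);
    for (int f = 0; f < nf; ++f) {
      float best; int arg;
      if (t1 > Jc) { best = st.bact(f); arg = -1; }
      else { best = -std::numeric_limits<float>::infinity(); arg = -1; }
      for (int t = t0; t < tc; ++t) {
        float v = net->conv(f, t);
        v = v > 0.0f ? v : 0.0f;
        if (v > best) { best = v; arg = t; }
      }
      st.x(w * nf + f) = best;
      st.pool_arg(w * nf + f) = arg;
    }
  }
  if (net->use_net)
    for (int d = 0; d < net->ndim; ++d)
      st.x(net->flat + d) = (float)nvec[d];

  st.h_pre = net->Wd * st.x + net->bd;
  st.h = st.h_pre;
  st.h.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  if (train && net->dropout > 0.0f) {
    st.dropmask.set_size(net->dunits);
    float keep = 1.0f - net->dropout;
    for (int i = 0; i < net->dunits; ++i) {
      float u = urand(net->rng, 0.0f, 1.0f);
      st.dropmask(i) = (u < keep) ? 1.0f / keep : 0.0f;
    }
    st.hdrop = st.h % st.dropmask;
  } else {
    st.dropmask.reset();
    st.hdrop = st.h;
  }

  // per-term class subnets
  st.a.set_size(net->T); st.z.set_size(net->T);
  if (net->units > 1) { st.mid_pre.resize(net->T); st.mid.resize(net->T); }
  for (int o = 0; o < net->T; ++o) {
    int t = net->cascade ? (int)net->topo_pf(o) : o;
    ClassLayer& c = net->cls[t];
    int idim = net->idim(t);
    fvec in(idim);
    in.head(net->dunits) = st.hdrop;
    if (net->cascade)
      for (uword i = 0; i < net->parents[t].n_elem; ++i)
        in(net->dunits + i) = st.a(net->parents[t](i));
    float z;
    if (net->units > 1) {
      st.mid_pre[t] = c.W1 * in + c.b1;
      st.mid[t] = st.mid_pre[t];
      st.mid[t].transform([](float v) { return v > 0.0f ? v : 0.0f; });
      z = dot(c.w2, st.mid[t]) + c.b2;
    } else {
      z = dot(c.w2, in) + c.b2;
    }
    st.z(t) = z;
    st.a(t) = 1.0f / (1.0f + std::exp(-z));
  }

  // recursive max-merge == max over the selected-descendant closure
  st.out.set_size(net->T);
  st.merge_arg.set_size(net->T);
  if (net->use_merge) {
    for (int t = 0; t < net->T; ++t) {
      const uvec& cl = net->closure[t];
      float best = -1.0f; int arg = t;
      for (uword i = 0; i < cl.n_elem; ++i)
        if (st.a(cl(i)) > best) { best = st.a(cl(i)); arg = (int)cl(i); }
      st.out(t) = best;
      st.merge_arg(t) = arg;
    }
  } else {
    st.out = st.a;
    for (int t = 0; t < net->T; ++t) st.merge_arg(t) = t;
  }
}

static double sample_loss(const fvec& out, const int* y, int T) {
  double s = 0.0;
  for (int t = 0; t < T; ++t) {
    double p = std::min(std::max((double)out(t), 1e-7), 1.0 - 1e-7);
    s += y[t] ? -std::log(p) : -std::log1p(-p);
  }
  return s / T;
}

static void zero_grads(Net* net) {
  net->gEt.zeros(net->edim, net->vocab + 1);
  net->gWc.zeros(net->nf, net->k * net->edim);
  net->gbc.zeros(net->nf);
  net->gWd.zeros(net->dunits, net->fdim);
  net->gbd.zeros(net->dunits);
  for (int t = 0; t < net->T; ++t) {
    ClassLayer& c = net->cls[t];
    if (net->units > 1) { c.gW1.zeros(size(c.W1)); c.gb1.zeros(c.b1.n_elem); }
    c.gw2.zeros(c.w2.n_elem); c.gb2 = 0.0f;
  }
}

// backward one sample, accumulating into g* (assumes forward_one just ran)
static void backward_one(Net* net, const int* idx, FwdState& st, const int* y) {
  int T = net->T, nf = net->nf, edim = net->edim, k = net->k;
  float invT = 1.0f / (float)T;

  // loss -> pre-sigmoid of the argmax term (stable (a - y) form), plus
  // activation-level gradient from cascade children
  fvec dz_direct(T, fill::zeros), da_extra(T, fill::zeros);
  for (int t = 0; t < T; ++t) {
    int j = st.merge_arg(t);
    dz_direct(j) += (st.a(j) - (float)y[t]) * invT;
  }
  fvec dh(net->dunits, fill::zeros);
  // children-first order so parents' da_extra is complete when visited
  for (int o = net->T - 1; o >= 0; --o) {
    int t = net->cascade ? (int)net->topo_pf(o) : o;
    ClassLayer& c = net->cls[t];
    float dz = dz_direct(t) + da_extra(t) * st.a(t) * (1.0f - st.a(t));
    if (dz == 0.0f) continue;
    int idim = net->idim(t);
    fvec in(idim);
    in.head(net->dunits) = st.hdrop;
    if (net->cascade)
      for (uword i = 0; i < net->parents[t].n_elem; ++i)
        in(net->dunits + i) = st.a(net->parents[t](i));
    fvec di;
    if (net->units > 1) {
      c.gw2 += dz * st.mid[t]; c.gb2 += dz;
      fvec dmid = dz * c.w2;
      for (int u = 0; u < net->units; ++u)
        if (st.mid_pre[t](u) <= 0.0f) dmid(u) = 0.0f;
      c.gW1 += dmid * in.t(); c.gb1 += dmid;
      di = c.W1.t() * dmid;
    } else {
      c.gw2 += dz * in; c.gb2 += dz;
      di = dz * c.w2;
    }
    dh += di.head(net->dunits);
    if (net->cascade)
      for (uword i = 0; i < net->parents[t].n_elem; ++i)
        da_extra(net->parents[t](i)) += di(net->dunits + i);
  }

  if (st.dropmask.n_elem) dh %= st.dropmask;
  fvec dh_pre = dh;
  for (int i = 0; i < net->dunits; ++i)
    if (st.h_pre(i) <= 0.0f) dh_pre(i) = 0.0f;
  net->gWd += dh_pre * st.x.t();
  net->gbd += dh_pre;
  fvec dx = net->Wd.t() * dh_pre;

  // pool backward: route to conv argmax / bias-only zone
  int Jc = st.Jc;
  if (Jc > 0) net->dconv.head_cols(Jc).zeros();
  fvec dbias(nf, fill::zeros);
  for (int w = 0; w < net->npool; ++w)
    for (int f = 0; f < nf; ++f) {
      float g = dx(w * nf + f);
      if (g == 0.0f) continue;
      int arg = st.pool_arg(w * nf + f);
      if (arg >= 0) {
        if (net->conv(f, arg) > 0.0f) net->dconv(f, arg) += g; // ReLU gate
      } else {
        if (net->bc(f) > 0.0f) dbias(f) += g;
      }
    }
  net->gbc += dbias;
  if (Jc > 0) {
    net->gbc += sum(net->dconv.head_cols(Jc), 1);
    net->gWc += net->dconv.head_cols(Jc) * net->col.head_cols(Jc).t();
    net->dcol.head_cols(Jc) = net->Wc.t() * net->dconv.head_cols(Jc);
    for (int j = 0; j < Jc; ++j) {
      const float* src = net->dcol.colptr(j);
      for (int p = 0; p < k; ++p) {
        int pos = j + p;
        int v = (pos < net->L) ? idx[pos] : 0;
        if (v > 0) {
          float* dst = net->gEt.colptr(v);
          const float* s = src + (size_t)p * edim;
          for (int d = 0; d < edim; ++d) dst[d] += s[d];
        }
      }
    }
  }
}

static void rms_update(fmat& w, fmat& g, fmat& v, float lr, float rho, float eps) {
  v = rho * v + (1.0f - rho) * square(g);
  w -= lr * g / (sqrt(v) + eps);
}
static void rms_update(fvec& w, fvec& g, fvec& v, float lr, float rho, float eps) {
  v = rho * v + (1.0f - rho) * square(g);
  w -= lr * g / (sqrt(v) + eps);
}

struct Snapshot {
  fmat Et, Wc, Wd; fvec bc, bd;
  std::vector<fmat> W1; std::vector<fvec> b1, w2; std::vector<float> b2;
};

static void take_snapshot(Net* net, Snapshot& s) {
  s.Et = net->Et; s.Wc = net->Wc; s.Wd = net->Wd; s.bc = net->bc; s.bd = net->bd;
  s.W1.resize(net->T); s.b1.resize(net->T); s.w2.resize(net->T); s.b2.resize(net->T);
  for (int t = 0; t < net->T; ++t) {
    s.W1[t] = net->cls[t].W1; s.b1[t] = net->cls[t].b1;
    s.w2[t] = net->cls[t].w2; s.b2[t] = net->cls[t].b2;
  }
}
static void restore_snapshot(Net* net, const Snapshot& s) {
  net->Et = s.Et; net->Wc = s.Wc; net->Wd = s.Wd; net->bc = s.bc; net->bd = s.bd;
  for (int t = 0; t < net->T; ++t) {
    net->cls[t].W1 = s.W1[t]; net->cls[t].b1 = s.b1[t];
    net->cls[t].w2 = s.w2[t]; net->cls[t].b2 = s.b2[t];
  }
}

// [[Rcpp::export(name = ".net_train")]]
Rcpp::NumericMatrix net_train(SEXP ptr_, Rcpp::IntegerMatrix idxm,
                              Rcpp::NumericMatrix netm, Rcpp::IntegerMatrix Y,
                              Rcpp::List cfg) {
  Rcpp::XPtr<Net> ptr(ptr_);
  Net* net = ptr.get();
  int n = idxm.nrow();
  if (n < 2) Rcpp::stop("need at least two samples to train");
  if (idxm.ncol() != net->L) Rcpp::stop("index matrix has wrong width");
  if (Y.ncol() != net->T) Rcpp::stop("label matrix does not match term set");
  if (net->use_net && netm.ncol() != net->ndim)
    Rcpp::stop("network-embedding matrix has wrong dimension");

  int epochs = cfg["max_epochs"];
  int bsize = cfg["batch_size"];
  float lr = (float)Rcpp::as<double>(cfg["learning_rate"]);
  float rho = (float)Rcpp::as<double>(cfg["rho"]);
  float eps = (float)Rcpp::as<double>(cfg["epsilon"]);
  double vfrac = cfg["validation_fraction"];
  int seed = cfg["seed"];
  bool verbose = cfg["verbose"];

  std::mt19937 trng((unsigned)seed + 1315423911u);
  net->rng.seed((unsigned)seed * 2654435761u + 17u); // dropout stream

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::shuffle(order.begin(), order.end(), trng);
  int nval = (int)std::lround(vfrac * n);
  if (n - nval < 1) Rcpp::stop("validation fraction leaves no training data");
  std::vector<int> tr(order.begin(), order.end() - nval);
  std::vector<int> va(order.end() - nval, order.end());

  // rmsprop state
  net->vEt.zeros(size(net->Et)); net->vWc.zeros(size(net->Wc));
  net->vWd.zeros(size(net->Wd)); net->vbc.zeros(net->nf); net->vbd.zeros(net->dunits);
  for (int t = 0; t < net->T; ++t) {
    ClassLayer& c = net->cls[t];
    if (net->units > 1) { c.vW1.zeros(size(c.W1)); c.vb1.zeros(c.b1.n_elem); }
    c.vw2.zeros(c.w2.n_elem); c.vb2 = 0.0f;
  }

  Rcpp::NumericMatrix history(epochs, 2);
  Snapshot best;
  double best_val = std::numeric_limits<double>::infinity();
  FwdState st;

  // buffer row copies (Rcpp matrices are column-major)
  std::vector<int> idxrow(net->L), yrow(net->T);
  std::vector<double> nrow(net->ndim);
  int ncopy = net->use_net ? net->ndim : 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), trng);
    double tloss = 0.0; long tcount = 0;
    for (size_t b0 = 0; b0 < tr.size(); b0 += bsize) {
      size_t b1 = std::min(b0 + (size_t)bsize, tr.size());
      zero_grads(net);
      for (size_t s = b0; s < b1; ++s) {
        int i = tr[s];
        for (int j = 0; j < net->L; ++j) idxrow[j] = idxm(i, j);
        for (int j = 0; j < ncopy; ++j) nrow[j] = netm(i, j);
        for (int j = 0; j < net->T; ++j) yrow[j] = Y(i, j);
        forward_one(net, idxrow.data(), nrow.data(), true, st);
        tloss += sample_loss(st.out, yrow.data(), net->T); ++tcount;
        backward_one(net, idxrow.data(), st, yrow.data());
      }
      float inv = 1.0f / (float)(b1 - b0);
      net->gEt *= inv; net->gWc *= inv; net->gbc *= inv;
      net->gWd *= inv; net->gbd *= inv;
      rms_update(net->Et, net->gEt, net->vEt, lr, rho, eps);
      net->Et.col(0).zeros();   // padding embedding stays zero
      rms_update(net->Wc, net->gWc, net->vWc, lr, rho, eps);
      rms_update(net->bc, net->gbc, net->vbc, lr, rho, eps);
      rms_update(net->Wd, net->gWd, net->vWd, lr, rho, eps);
      rms_update(net->bd, net->gbd, net->vbd, lr, rho, eps);
      for (int t = 0; t < net->T; ++t) {
        ClassLayer& c = net->cls[t];
        if (net->units > 1) {
          c.gW1 *= inv; c.gb1 *= inv;
          rms_update(c.W1, c.gW1, c.vW1, lr, rho, eps);
          rms_update(c.b1, c.gb1, c.vb1, lr, rho, eps);
        }
        c.gw2 *= inv; c.gb2 *= inv;
        rms_update(c.w2, c.gw2, c.vw2, lr, rho, eps);
        c.vb2 = rho * c.vb2 + (1.0f - rho) * c.gb2 * c.gb2;
        c.b2 -= lr * c.gb2 / (std::sqrt(c.vb2) + eps);
      }
    }
    double train_loss = tcount ? tloss / tcount : NA_REAL;

    double vloss = 0.0;
    for (int i : va) {
      for (int j = 0; j < net->L; ++j) idxrow[j] = idxm(i, j);
      for (int j = 0; j < ncopy; ++j) nrow[j] = netm(i, j);
      for (int j = 0; j < net->T; ++j) yrow[j] = Y(i, j);
      forward_one(net, idxrow.data(), nrow.data(), false, st);
      vloss += sample_loss(st.out, yrow.data(), net->T);
    }
    double val_loss = va.empty() ? train_loss : vloss / va.size();

    if (!std::isfinite(train_loss) || !std::isfinite(val_loss))
      Rcpp::stop("non-finite loss at epoch %d (train %f, validation %f); "
                 "try a lower learning rate", ep + 1, train_loss, val_loss);
    history(ep, 0) = train_loss;
    history(ep, 1) = val_loss;
    if (val_loss < best_val) { best_val = val_loss; take_snapshot(net, best); }
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << "/" << epochs
                  << "  train " << train_loss << "  val " << val_loss << "\n";
    Rcpp::checkUserInterrupt();
  }
  if (best_val < std::numeric_limits<double>::infinity())
    restore_snapshot(net, best);
  return history;
}

// raw per-term sigmoid activations (no merge, no dropout), one row per sample
// [[Rcpp::export(name = ".net_forward")]]
Rcpp::NumericMatrix net_forward(SEXP ptr_, Rcpp::IntegerMatrix idxm,
                                Rcpp::NumericMatrix netm) {
  Rcpp::XPtr<Net> ptr(ptr_);
  Net* net = ptr.get();
  int n = idxm.nrow();
  if (idxm.ncol() != net->L) Rcpp::stop("index matrix has wrong width");
  if (net->use_net && netm.ncol() != net->ndim)
    Rcpp::stop("network-embedding matrix has wrong dimension");
  Rcpp::NumericMatrix out(n, net->T);
  FwdState st;
  std::vector<int> idxrow(net->L);
  std::vector<double> nrow(net->ndim);
  int ncopy = net->use_net ? net->ndim : 0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < net->L; ++j) idxrow[j] = idxm(i, j);
    for (int j = 0; j < ncopy; ++j) nrow[j] = netm(i, j);
    forward_one(net, idxrow.data(), nrow.data(), false, st);
    for (int t = 0; t < net->T; ++t) out(i, t) = (double)st.a(t);
  }
  return out;
}

// [[Rcpp::export(name = ".net_get_weights")]]
Rcpp::List net_get_weights(SEXP ptr_) {
  Rcpp::XPtr<Net> ptr(ptr_);
  Net* net = ptr.get();
  Rcpp::List cl(net->T);
  for (int t = 0; t < net->T; ++t) {
    ClassLayer& c = net->cls[t];
    cl[t] = Rcpp::List::create(
      Rcpp::Named("W1") = Rcpp::wrap(conv_to<mat>::from(c.W1)),
      Rcpp::Named("b1") = Rcpp::wrap(conv_to<vec>::from(c.b1)),
      Rcpp::Named("w2") = Rcpp::wrap(conv_to<vec>::from(c.w2)),
      Rcpp::Named("b2") = (double)c.b2);
  }
  return Rcpp::List::create(
    Rcpp::Named("Et") = Rcpp::wrap(conv_to<mat>::from(net->Et)),
    Rcpp::Named("Wc") = Rcpp::wrap(conv_to<mat>::from(net->Wc)),
    Rcpp::Named("bc") = Rcpp::wrap(conv_to<vec>::from(net->bc)),
    Rcpp::Named("Wd") = Rcpp::wrap(conv_to<mat>::from(net->Wd)),
    Rcpp::Named("bd") = Rcpp::wrap(conv_to<vec>::from(net->bd)),
    Rcpp::Named("cls") = cl);
}

// [[Rcpp::export(name = ".net_set_weights")]]
void net_set_weights(SEXP ptr_, Rcpp::List w) {
  Rcpp::XPtr<Net> ptr(ptr_);
  Net* net = ptr.get();
  net->Et = conv_to<fmat>::from(Rcpp::as<mat>(w["Et"]));
  net->Wc = conv_to<fmat>::from(Rcpp::as<mat>(w["Wc"]));
  net->bc = conv_to<fvec>::from(Rcpp::as<vec>(w["bc"]));
  net->Wd = conv_to<fmat>::from(Rcpp::as<mat>(w["Wd"]));
  net->bd = conv_to<fvec>::from(Rcpp::as<vec>(w["bd"]));
  Rcpp::List cl = w["cls"];
  if ((int)cl.size() != net->T) Rcpp::stop("weight list does not match term set");
  for (int t = 0; t < net->T; ++t) {
    Rcpp::List e = cl[t];
    ClassLayer& c = net->cls[t];
    c.W1 = conv_to<fmat>::from(Rcpp::as<mat>(e["W1"]));
    c.b1 = conv_to<fvec>::from(Rcpp::as<vec>(e["b1"]));
    c.w2 = conv_to<fvec>::from(Rcpp::as<vec>(e["w2"]));
    c.b2 = (float)Rcpp::as<double>(e["b2"]);
  }
}
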