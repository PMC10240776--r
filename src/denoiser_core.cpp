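// Compiled core of the noise-prediction network: full forward pass and
// analytic backward pass, mirroring the reference R implementation in
// R/denoiser.R exactly (same layer order, layer-norm epsilon, softmax
// scaling, pair-tensor layout). Pair tensors are stored flattened with row
// index (j - 1) * n + i for the token pair (i, j), matching R's
// column-major vectorization. Parity with the R path is asserted in the
// test suite to 1e-10.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

struct Config {
  int n_blocks, c_s, c_p, n_heads, c_outer, c_tri, tf, c_head, n_rbf, d_time;
  double d_max, eps_dist, coord_scale;
  bool use_tri;
};

Config read_config(const List& cfg) {
  Config c;
  c.n_blocks = as<int>(cfg["n_blocks"]);
  c.c_s = as<int>(cfg["c_s"]);
  c.c_p = as<int>(cfg["c_p"]);
  c.n_heads = as<int>(cfg["n_heads"]);
  c.c_outer = as<int>(cfg["c_outer"]);
  c.c_tri = as<int>(cfg["c_tri"]);
  c.tf = as<int>(cfg["transition_factor"]);
  c.c_head = as<int>(cfg["c_head"]);
  c.n_rbf = as<int>(cfg["n_rbf"]);
  c.d_time = as<int>(cfg["d_time"]);
  c.d_max = as<double>(cfg["d_max"]);
  c.eps_dist = as<double>(cfg["epsilon_dist"]);
  c.coord_scale = as<double>(cfg["coord_scale"]);
  c.use_tri = as<bool>(cfg["use_triangular_update"]);
  return c;
}

// Parameter store: either a named R list of matrices/vectors (copy on
// fetch), or a flat double vector with a layout derived from a prototype
// list (zero-copy views; used by the training fast path). Gradients
// accumulate in a map (list mode) or a flat vector (flat mode).
struct Params {
  const List* src = nullptr;
  std::map<std::string, mat> grads;
  // flat mode
  double* base = nullptr;
  vec* gflat = nullptr;
  struct Slot { size_t off, nr, nc; bool is_mat; };
  std::map<std::string, Slot> layout;

  explicit Params(const List& p) : src(&p) {}

  Params(double* flat, vec& gacc, const List& proto)
      : base(flat), gflat(&gacc) {
    CharacterVector nms = proto.names();
    size_t off = 0;
    for (int i = 0; i < nms.size(); ++i) {
      std::string nm = as<std::string>(nms[i]);
      RObject o = proto[nm];
      Slot s;
      s.off = off;
      s.is_mat = Rf_isMatrix(o);
      if (s.is_mat) {
        s.nr = Rf_nrows(o); s.nc = Rf_ncols(o);
      } else {
        s.nr = 1; s.nc = Rf_length(o);
      }
      off += s.nr * s.nc;
      layout[nm] = s;
    }
  }

  mat get(const std::string& nm) const {
    if (base) {
      const Slot& s = layout.at(nm);
      if (s.is_mat)
        return mat(base + s.off, s.nr, s.nc, false, true);
      // bias vectors as 1 x k rows: flat storage is contiguous either way
      return mat(base + s.off, 1, s.nc, false, true);
    }
    RObject o = (*src)[nm];
    if (Rf_isMatrix(o)) return as<mat>(o);
    vec v = as<vec>(o);
    return mat(v).t();
  }
  void add(const std::string& nm, const mat& g) {
    if (base) {
      const Slot& s = layout.at(nm);
      vec gv = arma::vectorise(g);
      gflat->subvec(s.off, s.off + gv.n_elem - 1) += gv;
      return;
    }
    auto it = grads.find(nm);
    if (it == grads.end()) grads[nm] = g; else it->second += g;
  }
};

const double LN_EPS = 1e-5;

struct LNCache { mat xhat; vec inv; rowvec g; };

mat layernorm_fwd(const mat& x, const rowvec& g, const rowvec& b,
                  LNCache& cache) {
  vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  vec v = arma::mean(arma::square(xc), 1);
  cache.inv = 1.0 / arma::sqrt(v + LN_EPS);
  cache.xhat = xc.each_col() % cache.inv;
  cache.g = g;
  mat out = cache.xhat.each_row() % g;
  out.each_row() += b;
  return out;
}

mat layernorm_bwd(const LNCache& cache, const mat& dout,
                  rowvec& dg, rowvec& db) {
  dg = arma::sum(dout % cache.xhat, 0);
  db = arma::sum(dout, 0);
  mat dxhat = dout.each_row() % cache.g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % cache.xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= cache.xhat.each_col() % m2;
  return dx.each_col() % cache.inv;
}

mat softmax_rows(const mat& logits) {
  vec m = arma::max(logits, 1);
  mat e = arma::exp(logits.each_col() - m);
  vec s = arma::sum(e, 1);
  return e.each_col() / s;
}

mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// distance matrix of z (n x 3)
mat dist_mat(const mat& z) {
  int n = z.n_rows;
  mat d(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dd = arma::norm(z.row(i) - z.row(j), 2);
      d(i, j) = dd; d(j, i) = dd;
    }
  return d;
}

mat center_rows(const mat& x) {
  rowvec mu = arma::mean(x, 0);
  return x.each_row() - mu;
}

// ---- caches ----

struct AttnCache {
  LNCache ln_s, ln_p;
  mat ln_s_out, ln_p_out, q, k, v;
  std::vector<mat> P;
};

struct TransCache { LNCache ln; mat ln_out, h1, r, mask; };

struct OuterCache { LNCache ln; mat ln_out, a, b, O; };

struct TriCache {
  LNCache ln, ln2;
  mat ln_out, ga, pa, a, gb, pb, b, z, ln2_out, go, gated;
};

struct BlockCache {
  AttnCache at; TransCache st; OuterCache ou; TriCache tr; TransCache pt;
  mat single_in, pair_in_outer, pair_in_tri, pair_in_pt;
};

struct HeadCache {
  LNCache ln; mat psym, ln_out, h1, mask, Wmat, dclamp; mat z;
};

struct EmbedCache { mat fs, fp, rbf; rowvec temb; };

std::string bk(int k, const char* nm) {
  return "blk" + std::to_string(k + 1) + "." + nm;
}

// ---- forward pieces ----

mat rbf_embed(const mat& z, const Config& c) {
  int n = z.n_rows;
  mat d = dist_mat(z) / c.coord_scale;   // angstroms
  vec centers = arma::linspace(0.0, c.d_max, c.n_rbf);
  double width = c.n_rbf > 1 ? centers(1) - centers(0) : c.d_max;
  mat out(n * n, c.n_rbf);
  vec dv = arma::vectorise(d);           // column-major: (j-1)*n+i
  for (int m = 0; m < c.n_rbf; ++m)
    out.col(m) = arma::exp(-arma::square(dv - centers(m)) /
                           (2.0 * width * width));
  return out;
}

void embed_fwd(Params& P, const Config& c, const mat& fs, const mat& fp,
               const mat& z, const rowvec& temb, mat& single, mat& pair,
               EmbedCache& cache) {
  cache.fs = fs; cache.fp = fp; cache.temb = temb;
  cache.rbf = rbf_embed(z, c);
  single = fs * P.get("emb.Ws");
  single.each_row() += P.get("emb.bs").row(0);
  single.each_row() += temb * P.get("emb.Wts");
  pair = fp * P.get("emb.Wp");
  pair.each_row() += P.get("emb.bp").row(0);
  pair += cache.rbf * P.get("emb.Wrbf");
  pair.each_row() += temb * P.get("emb.Wtp");
}

void embed_bwd(Params& P, const Config& c, const EmbedCache& cache,
               const mat& dsingle, const mat& dpair) {
  P.add("emb.Wtp", mat(cache.temb.t() * arma::sum(dpair, 0)));
  P.add("emb.Wrbf", cache.rbf.t() * dpair);
  P.add("emb.Wp", cache.fp.t() * dpair);
  P.add("emb.bp", arma::sum(dpair, 0));
  P.add("emb.Wts", mat(cache.temb.t() * arma::sum(dsingle, 0)));
  P.add("emb.Ws", cache.fs.t() * dsingle);
  P.add("emb.bs", arma::sum(dsingle, 0));
}

mat attn_fwd(Params& P, int k, const Config& c, const mat& single,
             const mat& pair, int n, AttnCache& cache) {
  int h = c.n_heads, dh = c.c_s / h;
  cache.ln_s_out = layernorm_fwd(single, P.get(bk(k, "attn.ln_s.g")).row(0),
                                 P.get(bk(k, "attn.ln_s.b")).row(0),
                                 cache.ln_s);
  cache.ln_p_out = layernorm_fwd(pair, P.get(bk(k, "attn.ln_p.g")).row(0),
                                 P.get(bk(k, "attn.ln_p.b")).row(0),
                                 cache.ln_p);
  cache.q = cache.ln_s_out * P.get(bk(k, "attn.Wq"));
  cache.k = cache.ln_s_out * P.get(bk(k, "attn.Wk"));
  cache.v = cache.ln_s_out * P.get(bk(k, "attn.Wv"));
  mat bias = cache.ln_p_out * P.get(bk(k, "attn.Wb"));   // n^2 x h
  mat o(n, c.c_s);
  cache.P.resize(h);
  for (int m = 0; m < h; ++m) {
    mat qm = cache.q.cols(m * dh, (m + 1) * dh - 1);
    mat km = cache.k.cols(m * dh, (m + 1) * dh - 1);
    mat logits = qm * km.t() / std::sqrt((double)dh) +
      arma::reshape(bias.col(m), n, n);
    cache.P[m] = softmax_rows(logits);
    o.cols(m * dh, (m + 1) * dh - 1) =
      cache.P[m] * cache.v.cols(m * dh, (m + 1) * dh - 1);
  }
  return single + o * P.get(bk(k, "attn.Wo"));
}

void attn_bwd(Params& P, int k, const Config& c, const AttnCache& cache,
              const mat& dout, int n, mat& dsingle, mat& dpair_add) {
  int h = c.n_heads, dh = c.c_s / h;
  mat Wo = P.get(bk(k, "attn.Wo"));
  // recompute o for the Wo gradient
  mat o(n, c.c_s);
  for (int m = 0; m < h; ++m)
    o.cols(m * dh, (m + 1) * dh - 1) =
      cache.P[m] * cache.v.cols(m * dh, (m + 1) * dh - 1);
  P.add(bk(k, "attn.Wo"), o.t() * dout);
  mat do_ = dout * Wo.t();
  mat dq(n, c.c_s, arma::fill::zeros), dk(n, c.c_s, arma::fill::zeros),
      dv(n, c.c_s, arma::fill::zeros);
  mat dbias(n * n, h);
  for (int m = 0; m < h; ++m) {
    mat dom = do_.cols(m * dh, (m + 1) * dh - 1);
    const mat& Pm = cache.P[m];
    mat dP = dom * cache.v.cols(m * dh, (m + 1) * dh - 1).t();
    dv.cols(m * dh, (m + 1) * dh - 1) = Pm.t() * dom;
    vec rs = arma::sum(dP % Pm, 1);
    mat dlog = Pm % (dP.each_col() - rs);
    dq.cols(m * dh, (m + 1) * dh - 1) =
      dlog * cache.k.cols(m * dh, (m + 1) * dh - 1) / std::sqrt((double)dh);
    dk.cols(m * dh, (m + 1) * dh - 1) =
      dlog.t() * cache.q.cols(m * dh, (m + 1) * dh - 1) /
      std::sqrt((double)dh);
    dbias.col(m) = arma::vectorise(dlog);
  }
  P.add(bk(k, "attn.Wq"), cache.ln_s_out.t() * dq);
  P.add(bk(k, "attn.Wk"), cache.ln_s_out.t() * dk);
  P.add(bk(k, "attn.Wv"), cache.ln_s_out.t() * dv);
  P.add(bk(k, "attn.Wb"), cache.ln_p_out.t() * dbias);
  mat dln_s = dq * P.get(bk(k, "attn.Wq")).t() +
    dk * P.get(bk(k, "attn.Wk")).t() + dv * P.get(bk(k, "attn.Wv")).t();
  mat dln_p = dbias * P.get(bk(k, "attn.Wb")).t();
  rowvec dg, db;
  dsingle = dout + layernorm_bwd(cache.ln_s, dln_s, dg, db);
  P.add(bk(k, "attn.ln_s.g"), dg); P.add(bk(k, "attn.ln_s.b"), db);
  dpair_add = layernorm_bwd(cache.ln_p, dln_p, dg, db);
  P.add(bk(k, "attn.ln_p.g"), dg); P.add(bk(k, "attn.ln_p.b"), db);
}

mat transition_fwd(Params& P, const std::string& pre, const mat& x,
                   TransCache& cache) {
  cache.ln_out = layernorm_fwd(x, P.get(pre + "ln.g").row(0),
                               P.get(pre + "ln.b").row(0), cache.ln);
  cache.h1 = cache.ln_out * P.get(pre + "W1");
  cache.h1.each_row() += P.get(pre + "b1").row(0);
  cache.mask = arma::conv_to<mat>::from(cache.h1 > 0.0);
  cache.r = cache.h1 % cache.mask;
  mat out = cache.r * P.get(pre + "W2");
  out.each_row() += P.get(pre + "b2").row(0);
  return x + out;
}

mat transition_bwd(Params& P, const std::string& pre, const TransCache& cache,
                   const mat& dout) {
  P.add(pre + "W2", cache.r.t() * dout);
  P.add(pre + "b2", arma::sum(dout, 0));
  mat dr = (dout * P.get(pre + "W2").t()) % cache.mask;
  P.add(pre + "W1", cache.ln_out.t() * dr);
  P.add(pre + "b1", arma::sum(dr, 0));
  mat d1 = dr * P.get(pre + "W1").t();
  rowvec dg, db;
  mat dx = dout + layernorm_bwd(cache.ln, d1, dg, db);
  P.add(pre + "ln.g", dg); P.add(pre + "ln.b", db);
  return dx;
}

mat outer_fwd(Params& P, int k, const Config& c, const mat& single,
              const mat& pair, int n, OuterCache& cache) {
  int co = c.c_outer;
  cache.ln_out = layernorm_fwd(single, P.get(bk(k, "outer.ln.g")).row(0),
                               P.get(bk(k, "outer.ln.b")).row(0), cache.ln);
  cache.a = cache.ln_out * P.get(bk(k, "outer.Wa"));
  cache.b = cache.ln_out * P.get(bk(k, "outer.Wb"));
  cache.O.set_size(n * n, co * co);
  for (int v = 0; v < co; ++v)
    for (int u = 0; u < co; ++u) {
      // column (v*co + u): a(i,u) * b(j,v) at row (j-1)*n+i
      mat block = cache.a.col(u) * cache.b.col(v).t();  // n x n, (i,j)
      cache.O.col(v * co + u) = arma::vectorise(block);
    }
  mat upd = cache.O * P.get(bk(k, "outer.Wo"));
  upd.each_row() += P.get(bk(k, "outer.bo")).row(0);
  return pair + upd;
}

mat outer_bwd(Params& P, int k, const Config& c, const OuterCache& cache,
              const mat& dout, int n) {
  int co = c.c_outer;
  P.add(bk(k, "outer.Wo"), cache.O.t() * dout);
  P.add(bk(k, "outer.bo"), arma::sum(dout, 0));
  mat dO = dout * P.get(bk(k, "outer.Wo")).t();
  mat da(n, co, arma::fill::zeros), db(n, co, arma::fill::zeros);
  for (int v = 0; v < co; ++v)
    for (int u = 0; u < co; ++u) {
      mat dblock = arma::reshape(dO.col(v * co + u), n, n);  // (i,j)
      da.col(u) += dblock * cache.b.col(v);
      db.col(v) += dblock.t() * cache.a.col(u);
    }
  P.add(bk(k, "outer.Wa"), cache.ln_out.t() * da);
  P.add(bk(k, "outer.Wb"), cache.ln_out.t() * db);
  mat dln = da * P.get(bk(k, "outer.Wa")).t() +
    db * P.get(bk(k, "outer.Wb")).t();
  rowvec dg, dbv;
  mat dx = layernorm_bwd(cache.ln, dln, dg, dbv);
  P.add(bk(k, "outer.ln.g"), dg); P.add(bk(k, "outer.ln.b"), dbv);
  return dx;
}

mat tri_fwd(Params& P, int k, const Config& c, const mat& pair, int n,
            TriCache& cache) {
  int ct = c.c_tri;
  cache.ln_out = layernorm_fwd(pair, P.get(bk(k, "tri.ln.g")).row(0),
                               P.get(bk(k, "tri.ln.b")).row(0), cache.ln);
  mat ga_l = cache.ln_out * P.get(bk(k, "tri.Wga"));
  ga_l.each_row() += P.get(bk(k, "tri.bga")).row(0);
  cache.ga = sigmoid(ga_l);
  cache.pa = cache.ln_out * P.get(bk(k, "tri.Wpa"));
  cache.a = cache.ga % cache.pa;
  mat gb_l = cache.ln_out * P.get(bk(k, "tri.Wgb"));
  gb_l.each_row() += P.get(bk(k, "tri.bgb")).row(0);
  cache.gb = sigmoid(gb_l);
  cache.pb = cache.ln_out * P.get(bk(k, "tri.Wpb"));
  cache.b = cache.gb % cache.pb;
  cache.z.set_size(n * n, ct);
  for (int cc = 0; cc < ct; ++cc) {
    mat A = arma::reshape(cache.a.col(cc), n, n);
    mat B = arma::reshape(cache.b.col(cc), n, n);
    cache.z.col(cc) = arma::vectorise(A * B.t());
  }
  cache.ln2_out = layernorm_fwd(cache.z, P.get(bk(k, "tri.ln2.g")).row(0),
                                P.get(bk(k, "tri.ln2.b")).row(0), cache.ln2);
  mat go_l = cache.ln_out * P.get(bk(k, "tri.Wgo"));
  go_l.each_row() += P.get(bk(k, "tri.bgo")).row(0);
  cache.go = sigmoid(go_l);
  cache.gated = cache.go % cache.ln2_out;
  mat upd = cache.gated * P.get(bk(k, "tri.Wzo"));
  upd.each_row() += P.get(bk(k, "tri.bzo")).row(0);
  return pair + upd;
}

mat tri_bwd(Params& P, int k, const Config& c, const TriCache& cache,
            const mat& dout, int n) {
  int ct = c.c_tri;
  P.add(bk(k, "tri.Wzo"), cache.gated.t() * dout);
  P.add(bk(k, "tri.bzo"), arma::sum(dout, 0));
  mat dgated = dout * P.get(bk(k, "tri.Wzo")).t();
  mat dgo = (dgated % cache.ln2_out) % cache.go % (1.0 - cache.go);
  P.add(bk(k, "tri.Wgo"), cache.ln_out.t() * dgo);
  P.add(bk(k, "tri.bgo"), arma::sum(dgo, 0));
  mat dln = dgo * P.get(bk(k, "tri.Wgo")).t();
  rowvec dg2, db2;
  mat dz = layernorm_bwd(cache.ln2, dgated % cache.go, dg2, db2);
  P.add(bk(k, "tri.ln2.g"), dg2); P.add(bk(k, "tri.ln2.b"), db2);
  mat da(n * n, ct), db(n * n, ct);
  for (int cc = 0; cc < ct; ++cc) {
    mat A = arma::reshape(cache.a.col(cc), n, n);
    mat B = arma::reshape(cache.b.col(cc), n, n);
    mat dZ = arma::reshape(dz.col(cc), n, n);
    da.col(cc) = arma::vectorise(dZ * B);
    db.col(cc) = arma::vectorise(dZ.t() * A);
  }
  mat dga = (da % cache.pa) % cache.ga % (1.0 - cache.ga);
  mat dpa = da % cache.ga;
  mat dgb = (db % cache.pb) % cache.gb % (1.0 - cache.gb);
  mat dpb = db % cache.gb;
  P.add(bk(k, "tri.Wga"), cache.ln_out.t() * dga);
  P.add(bk(k, "tri.bga"), arma::sum(dga, 0));
  P.add(bk(k, "tri.Wpa"), cache.ln_out.t() * dpa);
  P.add(bk(k, "tri.Wgb"), cache.ln_out.t() * dgb);
  P.add(bk(k, "tri.bgb"), arma::sum(dgb, 0));
  P.add(bk(k, "tri.Wpb"), cache.ln_out.t() * dpb);
  dln += dga * P.get(bk(k, "tri.Wga")).t() +
    dpa * P.get(bk(k, "tri.Wpa")).t() +
    dgb * P.get(bk(k, "tri.Wgb")).t() +
    dpb * P.get(bk(k, "tri.Wpb")).t();
  rowvec dg, dbv;
  mat dx = dout + layernorm_bwd(cache.ln, dln, dg, dbv);
  P.add(bk(k, "tri.ln.g"), dg); P.add(bk(k, "tri.ln.b"), dbv);
  return dx;
}

arma::uvec transpose_perm(int n) {
  arma::uvec p(n * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      p(j * n + i) = (arma::uword)(i * n + j);
  return p;
}

mat head_fwd(Params& P, const Config& c, const mat& pair, const mat& z,
             int n, HeadCache& cache, mat& Wout) {
  cache.z = z;
  // symmetrize: rows (i,j) and (j,i)
  mat psym = 0.5 * (pair + pair.rows(transpose_perm(n)));
  cache.psym = psym;
  cache.ln_out = layernorm_fwd(psym, P.get("head.ln.g").row(0),
                               P.get("head.ln.b").row(0), cache.ln);
  cache.h1 = cache.ln_out * P.get("head.W1");
  cache.h1.each_row() += P.get("head.b1").row(0);
  cache.mask = arma::conv_to<mat>::from(cache.h1 > 0.0);
  mat r = cache.h1 % cache.mask;
  mat wvec = r * P.get("head.W2");
  wvec.each_row() += P.get("head.b2").row(0);
  mat W = arma::reshape(wvec.col(0), n, n);
  W.diag().zeros();
  cache.Wmat = W;
  mat d = dist_mat(z);
  cache.dclamp = arma::clamp(d, c.eps_dist * c.coord_scale,
                             arma::datum::inf);
  mat C = W / cache.dclamp;
  vec rs = arma::sum(C, 1);
  mat eps_raw = z.each_col() % rs;
  eps_raw -= C * z;
  Wout = W;
  return center_rows(eps_raw);
}

mat head_bwd(Params& P, const Config& c, const HeadCache& cache,
             const mat& d_eps, int n) {
  mat dpre = center_rows(d_eps);
  vec rsz = arma::sum(dpre % cache.z, 1);
  mat dC = arma::repmat(rsz, 1, n) - dpre * cache.z.t();
  mat dW = dC / cache.dclamp;
  dW.diag().zeros();
  mat dwvec = arma::vectorise(dW);
  mat r = cache.h1 % cache.mask;
  P.add("head.W2", r.t() * dwvec);
  P.add("head.b2", arma::sum(dwvec, 0));
  mat dr = (dwvec * P.get("head.W2").t()) % cache.mask;
  P.add("head.W1", cache.ln_out.t() * dr);
  P.add("head.b1", arma::sum(dr, 0));
  mat d1 = dr * P.get("head.W1").t();
  rowvec dg, db;
  mat dpsym = layernorm_bwd(cache.ln, d1, dg, db);
  P.add("head.ln.g", dg); P.add("head.ln.b", db);
  return 0.5 * (dpsym + dpsym.rows(transpose_perm(n)));
}

struct ForwardState {
  EmbedCache em;
  std::vector<BlockCache> blocks;
  HeadCache hd;
  mat eps_hat, W;
};

void model_forward(Params& P, const Config& c, const mat& fs, const mat& fp,
                   const mat& z, const rowvec& temb, ForwardState& st) {
  int n = z.n_rows;
  mat single, pair;
  embed_fwd(P, c, fs, fp, z, temb, single, pair, st.em);
  st.blocks.resize(c.n_blocks);
  for (int k = 0; k < c.n_blocks; ++k) {
    BlockCache& B = st.blocks[k];
    single = attn_fwd(P, k, c, single, pair, n, B.at);
    single = transition_fwd(P, bk(k, "strans."), single, B.st);
    pair = outer_fwd(P, k, c, single, pair, n, B.ou);
    if (c.use_tri) pair = tri_fwd(P, k, c, pair, n, B.tr);
    pair = transition_fwd(P, bk(k, "ptrans."), pair, B.pt);
    if (!single.is_finite() || !pair.is_finite())
      stop("non-finite activations in folding block %d", k + 1);
  }
  st.eps_hat = head_fwd(P, c, pair, z, n, st.hd, st.W);
}

void model_backward(Params& P, const Config& c, ForwardState& st,
                    const mat& d_eps) {
  int n = st.hd.z.n_rows;
  mat dpair = head_bwd(P, c, st.hd, d_eps, n);
  mat dsingle(n, c.c_s, arma::fill::zeros);
  for (int k = c.n_blocks - 1; k >= 0; --k) {
    BlockCache& B = st.blocks[k];
    dpair = transition_bwd(P, bk(k, "ptrans."), B.pt, dpair);
    if (c.use_tri) dpair = tri_bwd(P, k, c, B.tr, dpair, n);
    mat ds2 = outer_bwd(P, k, c, B.ou, dpair, n);
    dsingle += ds2;
    dsingle = transition_bwd(P, bk(k, "strans."), B.st, dsingle);
    mat ds, dp_add;
    attn_bwd(P, k, c, B.at, dsingle, n, ds, dp_add);
    dsingle = ds;
    dpair += dp_add;
  }
  embed_bwd(P, c, st.em, dsingle, dpair);
}

List grads_to_list(const Params& P, const List& params) {
  CharacterVector nms = params.names();
  List out(nms.size());
  for (int i = 0; i < nms.size(); ++i) {
    std::string nm = as<std::string>(nms[i]);
    auto it = P.grads.find(nm);
    RObject proto = params[nm];
    if (it == P.grads.end()) {
      if (Rf_isMatrix(proto)) {
        NumericMatrix pm(proto);
        out[i] = NumericMatrix(pm.nrow(), pm.ncol());
      } else {
        out[i] = NumericVector(Rf_length(proto));
      }
    } else {
      const mat& g = it->second;
      if (Rf_isMatrix(proto)) {
        out[i] = wrap(g);
      } else {
        rowvec r = g.row(0);                        // 1 x k row -> bare vector
        out[i] = NumericVector(r.begin(), r.end());
      }
    }
  }
  out.names() = nms;
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_predict")]]
List cpp_predict(List params, List config, arma::mat fs, arma::mat fp,
                 arma::mat z, arma::rowvec temb) {
  Config c = read_config(config);
  Params P(params);
  ForwardState st;
  model_forward(P, c, fs, fp, z, temb, st);
  return List::create(_["eps_hat"] = st.eps_hat, _["W"] = st.W);
}

// [[Rcpp::export(name = ".cpp_loss_grad")]]
List cpp_loss_grad(List params, List config, arma::mat fs, arma::mat fp,
                   arma::mat x, arma::mat eps, double alpha, double sigma,
                   double gamma_prime, arma::rowvec temb, bool average_atoms) {
  Config c = read_config(config);
  Params P(params);
  mat z = alpha * x + sigma * eps;
  ForwardState st;
  model_forward(P, c, fs, fp, z, temb, st);
  mat r = st.eps_hat - eps;
  double scale = average_atoms ? 1.0 / x.n_rows : 1.0;
  double loss = 0.5 * gamma_prime * arma::accu(r % r) * scale;
  if (!std::isfinite(loss))
    stop("non-finite diffusion loss (model output diverged)");
  model_backward(P, c, st, (gamma_prime * scale) * r);
  return List::create(_["loss"] = loss,
                      _["grads"] = grads_to_list(P, params));
}

// Batched variant: one shared system (features), several (x, eps, t) draws;
// returns the batch-mean loss and batch-mean gradients in one crossing of
// the R/C++ boundary.
// [[Rcpp::export(name = ".cpp_loss_grad_batch")]]
List cpp_loss_grad_batch(List params, List config, arma::mat fs,
                         arma::mat fp, List xs, List epss,
                         arma::vec alphas, arma::vec sigmas,
                         arma::vec gamma_primes, arma::mat tembs,
                         bool average_atoms) {
  Config c = read_config(config);
  Params P(params);
  int B = xs.size();
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    mat x = as<mat>(xs[b]);
    mat eps = as<mat>(epss[b]);
    mat z = alphas(b) * x + sigmas(b) * eps;
    ForwardState st;
    model_forward(P, c, fs, fp, z, tembs.row(b), st);
    mat r = st.eps_hat - eps;
    double scale = (average_atoms ? 1.0 / x.n_rows : 1.0) / B;
    double lb = 0.5 * gamma_primes(b) * arma::accu(r % r) * scale;
    if (!std::isfinite(lb))
      stop("non-finite diffusion loss (model output diverged)");
    loss += lb;
    model_backward(P, c, st, (gamma_primes(b) * scale) * r);
  }
  return List::create(_["loss"] = loss,
                      _["grads"] = grads_to_list(P, params));
}

// Training fast path: parameters as one flat vector (layout from the
// prototype list), gradients returned flat, no per-call marshalling.
// [[Rcpp::export(name = ".cpp_loss_grad_batch_flat")]]
List cpp_loss_grad_batch_flat(NumericVector pflat, List proto, List config,
                              arma::mat fs, arma::mat fp, List xs,
                              List epss, arma::vec alphas, arma::vec sigmas,
                              arma::vec gamma_primes, arma::mat tembs,
                              bool average_atoms) {
  Config c = read_config(config);
  vec gacc(pflat.size(), arma::fill::zeros);
  Params P(pflat.begin(), gacc, proto);
  int B = xs.size();
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    mat x = as<mat>(xs[b]);
    mat eps = as<mat>(epss[b]);
    mat z = alphas(b) * x + sigmas(b) * eps;
    ForwardState st;
    model_forward(P, c, fs, fp, z, tembs.row(b), st);
    mat r = st.eps_hat - eps;
    double scale = (average_atoms ? 1.0 / x.n_rows : 1.0) / B;
    double lb = 0.5 * gamma_primes(b) * arma::accu(r % r) * scale;
    if (!std::isfinite(lb))
      stop("non-finite diffusion loss (model output diverged)");
    loss += lb;
    model_backward(P, c, st, (gamma_primes(b) * scale) * r);
  }
  return List::create(_["loss"] = loss, _["gflat"] = wrap(gacc));
}

// Flat-parameter batched forward-only loss (validation fast path).
// [[Rcpp::export(name = ".cpp_loss_batch_flat")]]
double cpp_loss_batch_flat(NumericVector pflat, List proto, List config,
                           arma::mat fs, arma::mat fp, List xs, List epss,
                           arma::vec alphas, arma::vec sigmas,
                           arma::vec gamma_primes, arma::mat tembs,
                           bool average_atoms) {
  Config c = read_config(config);
  vec dummy;
  Params P(pflat.begin(), dummy, proto);
  int B = xs.size();
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    mat x = as<mat>(xs[b]);
    mat eps = as<mat>(epss[b]);
    mat z = alphas(b) * x + sigmas(b) * eps;
    ForwardState st;
    model_forward(P, c, fs, fp, z, tembs.row(b), st);
    mat r = st.eps_hat - eps;
    double scale = (average_atoms ? 1.0 / x.n_rows : 1.0) / B;
    loss += 0.5 * gamma_primes(b) * arma::accu(r % r) * scale;
  }
  return loss;
}

// One Adam step with linear warm-up plus EMA tracking, updating all state
// vectors in place. Returns the learning rate used.
// [[Rcpp::export(name = ".cpp_adam_ema_step")]]
double cpp_adam_ema_step(NumericVector pflat, NumericVector m,
                         NumericVector v, NumericVector ema,
                         NumericVector gflat, int step, double base_lr,
                         int warmup_steps, double beta1, double beta2,
                         double eps, double ema_decay) {
  double lr = step < warmup_steps ? base_lr * step / warmup_steps : base_lr;
  double bc1 = 1.0 - std::pow(beta1, step);
  double bc2 = 1.0 - std::pow(beta2, step);
  int n = pflat.size();
  for (int i = 0; i < n; ++i) {
    double g = gflat[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * g;
    v[i] = beta2 * v[i] + (1.0 - beta2) * g * g;
    pflat[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
    ema[i] = ema_decay * ema[i] + (1.0 - ema_decay) * pflat[i];
  }
  return lr;
}

// Batched forward-only loss (validation).
// [[Rcpp::export(name = ".cpp_loss_batch")]]
double cpp_loss_batch(List params, List config, arma::mat fs, arma::mat fp,
                      List xs, List epss, arma::vec alphas,
                      arma::vec sigmas, arma::vec gamma_primes,
                      arma::mat tembs, bool average_atoms) {
  Config c = read_config(config);
  Params P(params);
  int B = xs.size();
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    mat x = as<mat>(xs[b]);
    mat eps = as<mat>(epss[b]);
    mat z = alphas(b) * x + sigmas(b) * eps;
    ForwardState st;
    model_forward(P, c, fs, fp, z, tembs.row(b), st);
    mat r = st.eps_hat - eps;
    double scale = (average_atoms ? 1.0 / x.n_rows : 1.0) / B;
    loss += 0.5 * gamma_primes(b) * arma::accu(r % r) * scale;
  }
  return loss;
}
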