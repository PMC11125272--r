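// Core multibody engine: augmented-Lagrangian index-3 formulation in mixed
// (natural + relative angle) coordinates, Newmark integration with velocity
// and acceleration projections, analytic sphere-vs-polynomial-surface contact
// with the Flores normal force model, and static equilibrium initialization.
//
// Coordinate layout: each body owns 12 natural coordinates (reference point r
// followed by the three columns u, v, w of its rotation matrix); relative
// angle coordinates are appended after all body blocks.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double EPS_DDOT0 = 1e-6;   // grazing-onset threshold for delta-dot-0

// ---------------------------------------------------------------------------
// small rotation helpers
// ---------------------------------------------------------------------------

static mat33 skew3(const vec3 &a) {
  mat33 S;
  S(0,0)=0;     S(0,1)=-a(2); S(0,2)= a(1);
  S(1,0)= a(2); S(1,1)=0;     S(1,2)=-a(0);
  S(2,0)=-a(1); S(2,1)= a(0); S(2,2)=0;
  return S;
}

static mat33 rot_axis(const vec3 &a, double th) {
  // Rodrigues formula, unit axis a
  mat33 S = skew3(a);
  return eye(3,3) + std::sin(th)*S + (1.0-std::cos(th))*(S*S);
}

static mat33 rot_x(double t){ vec3 a = {1,0,0}; return rot_axis(a,t); }
static mat33 rot_y(double t){ vec3 a = {0,1,0}; return rot_axis(a,t); }
static mat33 rot_z(double t){ vec3 a = {0,0,1}; return rot_axis(a,t); }

static vec3 axial3(const mat33 &A) {
  vec3 v;
  v(0) = 0.5*(A(2,1)-A(1,2));
  v(1) = 0.5*(A(0,2)-A(2,0));
  v(2) = 0.5*(A(1,0)-A(0,1));
  return v;
}

// ---------------------------------------------------------------------------
// model description (parsed once per entry point from an R list)
// ---------------------------------------------------------------------------

struct FixPoint   { int body; vec3 local; vec3 target; };
struct Coincid    { int bodyA; vec3 localA; int bodyB; vec3 localB; };
struct OrientEuler{ int body; ivec3 idx; mat33 R0; };  // idx: 0-based coord indices of the 3 angles
struct OrientRel  { int bodyA; int bodyB; int idx; vec3 axis; mat33 R0; };
struct Driver     { int coord; };                      // 0-based
struct Spring     { int bodyA; vec3 localA; int bodyB; vec3 localB;
                    double k, l0, c; };
struct Contact    { int sphere_body; vec3 center; double radius;
                    int surf_body; mat33 Rs; vec3 os;
                    mat coef;           // 5x5, coef(i,j) multiplies x^i y^j, i+j<=4
                    vec4 dom;           // xlo xhi ylo yhi
                    double kn, p, eps; };

struct Model {
  int n_bodies, n_extra, n;      // n = 12*n_bodies + n_extra
  mat M;                          // constant mass matrix (n x n)
  vec Qg;                         // constant gravity generalized force
  std::vector<int> rigid;         // body indices with rigid-body constraints
  std::vector<FixPoint> fixpts;
  std::vector<Coincid> coinc;
  std::vector<OrientEuler> oeuler;
  std::vector<OrientRel> orel;
  std::vector<Driver> drivers;
  std::vector<Spring> springs;
  std::vector<Contact> contacts;
  double alpha;
  int m;                          // constraint rows
};

static vec3 as_vec3(SEXP s) { Rcpp::NumericVector v(s); vec3 o; o(0)=v[0]; o(1)=v[1]; o(2)=v[2]; return o; }
static mat33 as_mat33(SEXP s) { Rcpp::NumericMatrix m(s); mat33 o; for(int i=0;i<3;i++) for(int j=0;j<3;j++) o(i,j)=m(i,j); return o; }

static Model parse_model(const Rcpp::List &ml) {
  Model M;
  M.n_bodies = Rcpp::as<int>(ml["n_bodies"]);
  M.n_extra  = Rcpp::as<int>(ml["n_extra"]);
  M.n = 12*M.n_bodies + M.n_extra;
  M.M  = Rcpp::as<mat>(ml["M"]);
  M.Qg = Rcpp::as<vec>(ml["Qg"]);
  M.alpha = Rcpp::as<double>(ml["alpha"]);

  Rcpp::IntegerVector rb = ml["rigid"];
  for (int i=0;i<rb.size();++i) M.rigid.push_back(rb[i]-1);

  Rcpp::List L;
  L = ml["fixpoints"];
  for (int i=0;i<L.size();++i) { Rcpp::List e=L[i];
    FixPoint f; f.body=Rcpp::as<int>(e["body"])-1; f.local=as_vec3(e["local"]); f.target=as_vec3(e["target"]);
    M.fixpts.push_back(f); }
  L = ml["coincidences"];
  for (int i=0;i<L.size();++i) { Rcpp::List e=L[i];
    Coincid c; c.bodyA=Rcpp::as<int>(e["bodyA"])-1; c.localA=as_vec3(e["localA"]);
    c.bodyB=Rcpp::as<int>(e["bodyB"])-1; c.localB=as_vec3(e["localB"]);
    M.coinc.push_back(c); }
  L = ml["orient_euler"];
  for (int i=0;i<L.size();++i) { Rcpp::List e=L[i];
    OrientEuler o; o.body=Rcpp::as<int>(e["body"])-1;
    Rcpp::IntegerVector ix=e["idx"]; for(int k=0;k<3;k++) o.idx(k)=ix[k]-1;
    o.R0=as_mat33(e["R0"]); M.oeuler.push_back(o); }
  L = ml["orient_rel"];
  for (int i=0;i<L.size();++i) { Rcpp::List e=L[i];
    OrientRel o; o.bodyA=Rcpp::as<int>(e["bodyA"])-1; o.bodyB=Rcpp::as<int>(e["bodyB"])-1;
    o.idx=Rcpp::as<int>(e["idx"])-1; o.axis=as_vec3(e["axis"]); o.axis/=norm(o.axis);
    o.R0=as_mat33(e["R0"]); M.orel.push_back(o); }
  L = ml["drivers"];
  for (int i=0;i<L.size();++i) { Rcpp::List e=L[i];
    Driver d; d.coord=Rcpp::as<int>(e["coord"])-1; M.drivers.push_back(d); }
  L = ml["springs"];
  for (int i=0;i<L.size();++i) { Rcpp::List e=L[i];
    Spring s; s.bodyA=Rcpp::as<int>(e["bodyA"])-1; s.localA=as_vec3(e["localA"]);
    s.bodyB=Rcpp::as<int>(e["bodyB"])-1; s.localB=as_vec3(e["localB"]);
    s.k=Rcpp::as<double>(e["k"]); s.l0=Rcpp::as<double>(e["l0"]); s.c=Rcpp::as<double>(e["c"]);
    M.springs.push_back(s); }
  L = ml["contacts"];
  for (int i=0;i<L.size();++i) { Rcpp::List e=L[i];
    Contact c; c.sphere_body=Rcpp::as<int>(e["sphere_body"])-1; c.center=as_vec3(e["center"]);
    c.radius=Rcpp::as<double>(e["radius"]); c.surf_body=Rcpp::as<int>(e["surf_body"])-1;
    c.Rs=as_mat33(e["Rs"]); c.os=as_vec3(e["os"]); c.coef=Rcpp::as<mat>(e["coef"]);
    Rcpp::NumericVector d=e["dom"]; for(int k=0;k<4;k++) c.dom(k)=d[k];
    c.kn=Rcpp::as<double>(e["kn"]); c.p=Rcpp::as<double>(e["p"]); c.eps=Rcpp::as<double>(e["eps"]);
    M.contacts.push_back(c); }

  M.m = 6*(int)M.rigid.size() + 3*(int)M.fixpts.size() + 3*(int)M.coinc.size()
      + 3*(int)M.oeuler.size() + 3*(int)M.orel.size() + (int)M.drivers.size();
  return M;
}

// ---------------------------------------------------------------------------
// body kinematics helpers
// ---------------------------------------------------------------------------

static inline int bbase(int body) { return 12*body; }

static mat33 body_R(const vec &q, int body) {
  int b = bbase(body);
  mat33 R;
  for (int j=0;j<3;j++) for (int i=0;i<3;i++) R(i,j) = q(b+3+3*j+i);
  return R;
}

static vec3 point_pos(const vec &q, int body, const vec3 &a) {
  int b = bbase(body);
  vec3 p;
  for (int i=0;i<3;i++)
    p(i) = q(b+i) + a(0)*q(b+3+i) + a(1)*q(b+6+i) + a(2)*q(b+9+i);
  return p;
}

// also works on qdot (linear map)
static vec3 point_vel(const vec &qd, int body, const vec3 &a) { return point_pos(qd, body, a); }

// Q += J^T f for a point force f applied at body local point a
static void add_point_force(vec &Q, int body, const vec3 &a, const vec3 &f) {
  if (body < 0) return;
  int b = bbase(body);
  double e[4] = {1.0, a(0), a(1), a(2)};
  for (int blk=0; blk<4; ++blk)
    for (int i=0;i<3;i++) Q(b+3*blk+i) += e[blk]*f(i);
}

// K += sign * J_A^T Kd J_B  (3x3 block pattern over the two bodies)
static void add_pair_block(mat &K, int bodyA, const vec3 &aA,
                           int bodyB, const vec3 &aB, const mat33 &Kd, double sign) {
  if (bodyA < 0 || bodyB < 0) return;
  int bA = bbase(bodyA), bB = bbase(bodyB);
  double eA[4] = {1.0, aA(0), aA(1), aA(2)};
  double eB[4] = {1.0, aB(0), aB(1), aB(2)};
  for (int i=0;i<4;i++) for (int j=0;j<4;j++) {
    double w = sign*eA[i]*eB[j];
    if (w == 0.0) continue;
    K.submat(bA+3*i, bB+3*j, bA+3*i+2, bB+3*j+2) += w*Kd;
  }
}

// ---------------------------------------------------------------------------
// polynomial surface: evaluation and closest point
// ---------------------------------------------------------------------------

static void poly_eval(const mat &C, double x, double y,
                      double *z, double *zx=nullptr, double *zy=nullptr,
                      double *zxx=nullptr, double *zxy=nullptr, double *zyy=nullptr) {
  int d = (int)C.n_rows; // 5 for quartic
  double px[8], py[8];
  px[0]=1; py[0]=1;
  for (int i=1;i<d;i++){ px[i]=px[i-1]*x; py[i]=py[i-1]*y; }
  double v=0, vx=0, vy=0, vxx=0, vxy=0, vyy=0;
  for (int i=0;i<d;i++) for (int j=0;j<d-i;j++) {
    double c = C(i,j);
    if (c == 0.0) continue;
    v += c*px[i]*py[j];
    if (i>=1) vx += c*i*px[i-1]*py[j];
    if (j>=1) vy += c*j*px[i]*py[j-1];
    if (i>=2) vxx += c*i*(i-1)*px[i-2]*py[j];
    if (i>=1 && j>=1) vxy += c*i*j*px[i-1]*py[j-1];
    if (j>=2) vyy += c*j*(j-1)*px[i]*py[j-2];
  }
  *z=v; if(zx)*zx=vx; if(zy)*zy=vy; if(zxx)*zxx=vxx; if(zxy)*zxy=vxy; if(zyy)*zyy=vyy;
}

// Closest point on z = P(x,y) to a 3D point cs (surface frame), damped Newton
// on the stationarity conditions of the squared distance, seeded at (u0,v0).
static bool poly_closest(const mat &C, const vec3 &cs, double u0, double v0,
                         double &u, double &v, int maxit=50) {
  u=u0; v=v0;
  double mu = 0.0;
  double z,zx,zy,zxx,zxy,zyy;
  for (int it=0; it<maxit; ++it) {
    poly_eval(C,u,v,&z,&zx,&zy,&zxx,&zxy,&zyy);
    double rz = z - cs(2);
    double g1 = (u-cs(0)) + rz*zx;
    double g2 = (v-cs(1)) + rz*zy;
    double gn = std::max(std::fabs(g1), std::fabs(g2));
    if (gn < 1e-13) return true;
    double h11 = 1.0 + zx*zx + rz*zxx;
    double h12 = zx*zy + rz*zxy;
    double h22 = 1.0 + zy*zy + rz*zyy;
    // Levenberg damping if the Hessian is not positive definite
    double det = h11*h22 - h12*h12;
    if (h11 <= 0 || det <= 0) {
      double add = std::fabs(std::min(h11, det)) + 1e-3;
      h11 += add; h22 += add; det = h11*h22 - h12*h12;
    }
    if (mu > 0) { h11 += mu; h22 += mu; det = h11*h22 - h12*h12; }
    double du = -( h22*g1 - h12*g2)/det;
    double dv = -(-h12*g1 + h11*g2)/det;
    double sn = std::sqrt(du*du+dv*dv);
    if (sn > 0.02) { du *= 0.02/sn; dv *= 0.02/sn; } // trust-region style cap
    u += du; v += dv;
    if (sn < 1e-14) return true;
  }
  // accept if gradient is small-ish (flat quartics converge fast; this is a guard)
  poly_eval(C,u,v,&z,&zx,&zy);
  double rz = z - cs(2);
  double g1 = (u-cs(0)) + rz*zx, g2 = (v-cs(1)) + rz*zy;
  return std::max(std::fabs(g1), std::fabs(g2)) < 1e-8;
}

// [[Rcpp::export(name = ".cpp_poly_closest")]]
Rcpp::List cpp_poly_closest(const arma::mat &coef, const arma::vec &center,
                            double u0, double v0) {
  vec3 cs; cs(0)=center(0); cs(1)=center(1); cs(2)=center(2);
  double u,v;
  bool ok = poly_closest(coef, cs, u0, v0, u, v);
  double z,zx,zy;
  poly_eval(coef,u,v,&z,&zx,&zy);
  vec3 p = {u,v,z};
  double dist = norm(cs-p);
  vec3 nrm = {-zx,-zy,1.0};   // surface normal (+z side)
  nrm /= norm(nrm);
  return Rcpp::List::create(
    Rcpp::Named("u")=u, Rcpp::Named("v")=v, Rcpp::Named("z")=z,
    Rcpp::Named("point")=Rcpp::NumericVector::create(p(0),p(1),p(2)),
    Rcpp::Named("distance")=dist,
    Rcpp::Named("normal")=Rcpp::NumericVector::create(nrm(0),nrm(1),nrm(2)),
    Rcpp::Named("converged")=ok);
}

// ---------------------------------------------------------------------------
// constraint assembly
// ---------------------------------------------------------------------------

// Euler Z-X-Y wrapper: B = Rz(a1) Rx(a2) Ry(a3) R0 and derivative pieces
struct EulerB {
  mat33 B, d1, d2, d3;      // value and first partials
  mat33 A1, A2, P3;         // Rz, Rx, Ry*R0
};

static EulerB euler_zxy(double a1, double a2, double a3, const mat33 &R0) {
  EulerB e;
  e.A1 = rot_z(a1); e.A2 = rot_x(a2); e.P3 = rot_y(a3)*R0;
  static const vec3 ex = {1,0,0}, ey = {0,1,0}, ez = {0,0,1};
  mat33 Sz = skew3(ez), Sx = skew3(ex), Sy = skew3(ey);
  e.B  = e.A1*e.A2*e.P3;
  e.d1 = Sz*e.B;
  e.d2 = e.A1*Sx*e.A2*e.P3;
  e.d3 = e.A1*e.A2*Sy*e.P3;
  return e;
}

// Assemble Phi and (optionally) Phiq.  dpos: prescribed driver positions.
static void assemble_phi(const Model &mod, const vec &q, const vec &dpos,
                         vec &phi, mat *Phiq) {
  phi.zeros(mod.m);
  if (Phiq) Phiq->zeros(mod.m, mod.n);
  int row = 0;

  for (int b : mod.rigid) {
    int base = bbase(b);
    vec3 u,v,w;
    for (int i=0;i<3;i++){ u(i)=q(base+3+i); v(i)=q(base+6+i); w(i)=q(base+9+i); }
    phi(row+0)=dot(u,u)-1; phi(row+1)=dot(v,v)-1; phi(row+2)=dot(w,w)-1;
    phi(row+3)=dot(u,v);   phi(row+4)=dot(u,w);   phi(row+5)=dot(v,w);
    if (Phiq) {
      mat &J = *Phiq;
      for (int i=0;i<3;i++) {
        J(row+0, base+3+i)=2*u(i);
        J(row+1, base+6+i)=2*v(i);
        J(row+2, base+9+i)=2*w(i);
        J(row+3, base+3+i)=v(i); J(row+3, base+6+i)=u(i);
        J(row+4, base+3+i)=w(i); J(row+4, base+9+i)=u(i);
        J(row+5, base+6+i)=w(i); J(row+5, base+9+i)=v(i);
      }
    }
    row += 6;
  }

  for (const FixPoint &f : mod.fixpts) {
    vec3 p = point_pos(q, f.body, f.local);
    for (int i=0;i<3;i++) phi(row+i) = p(i)-f.target(i);
    if (Phiq) {
      int base = bbase(f.body);
      double e[4] = {1.0, f.local(0), f.local(1), f.local(2)};
      for (int blk=0;blk<4;blk++) for (int i=0;i<3;i++)
        (*Phiq)(row+i, base+3*blk+i) = e[blk];
    }
    row += 3;
  }

  for (const Coincid &c : mod.coinc) {
    vec3 pA = point_pos(q, c.bodyA, c.localA);
    vec3 pB = point_pos(q, c.bodyB, c.localB);
    for (int i=0;i<3;i++) phi(row+i) = pA(i)-pB(i);
    if (Phiq) {
      int bA = bbase(c.bodyA), bB = bbase(c.bodyB);
      double eA[4] = {1.0, c.localA(0), c.localA(1), c.localA(2)};
      double eB[4] = {1.0, c.localB(0), c.localB(1), c.localB(2)};
      for (int blk=0;blk<4;blk++) for (int i=0;i<3;i++) {
        (*Phiq)(row+i, bA+3*blk+i) += eA[blk];
        (*Phiq)(row+i, bB+3*blk+i) -= eB[blk];
      }
    }
    row += 3;
  }

  for (const OrientEuler &o : mod.oeuler) {
    EulerB e = euler_zxy(q(o.idx(0)), q(o.idx(1)), q(o.idx(2)), o.R0);
    mat33 R = body_R(q, o.body);
    vec3 ph = axial3(e.B.t()*R);
    for (int i=0;i<3;i++) phi(row+i) = ph(i);
    if (Phiq) {
      int base = bbase(o.body);
      // derivative wrt rotation columns r_j of the body:
      // Phi0 = (b2.r1 - b1.r2)/2 ; Phi1 = (b0.r2 - b2.r0)/2 ; Phi2 = (b1.r0 - b0.r1)/2
      vec3 b0 = e.B.col(0), b1 = e.B.col(1), b2 = e.B.col(2);
      for (int i=0;i<3;i++) {
        (*Phiq)(row+0, base+6+i) += 0.5*b2(i); (*Phiq)(row+0, base+9+i) -= 0.5*b1(i);
        (*Phiq)(row+1, base+9+i) += 0.5*b0(i); (*Phiq)(row+1, base+3+i) -= 0.5*b2(i);
        (*Phiq)(row+2, base+3+i) += 0.5*b1(i); (*Phiq)(row+2, base+6+i) -= 0.5*b0(i);
      }
      const mat33 *dB[3] = {&e.d1, &e.d2, &e.d3};
      for (int a=0;a<3;a++) {
        vec3 da = axial3(dB[a]->t()*R);
        for (int i=0;i<3;i++) (*Phiq)(row+i, o.idx(a)) = da(i);
      }
    }
    row += 3;
  }

  for (const OrientRel &o : mod.orel) {
    double th = q(o.idx);
    mat33 G = rot_axis(o.axis, th);
    mat33 Rf = body_R(q, o.bodyA), Rt = body_R(q, o.bodyB);
    mat33 H = G*o.R0;             // Bk = Rf * H
    mat33 Bk = Rf*H;
    vec3 ph = axial3(Bk.t()*Rt);
    for (int i=0;i<3;i++) phi(row+i) = ph(i);
    if (Phiq) {
      int bA = bbase(o.bodyA), bB = bbase(o.bodyB);
      vec3 b0 = Bk.col(0), b1 = Bk.col(1), b2 = Bk.col(2);
      vec3 t0 = Rt.col(0), t1 = Rt.col(1), t2 = Rt.col(2);
      for (int i=0;i<3;i++) {
        // wrt tibia columns
        (*Phiq)(row+0, bB+6+i) += 0.5*b2(i); (*Phiq)(row+0, bB+9+i) -= 0.5*b1(i);
        (*Phiq)(row+1, bB+9+i) += 0.5*b0(i); (*Phiq)(row+1, bB+3+i) -= 0.5*b2(i);
        (*Phiq)(row+2, bB+3+i) += 0.5*b1(i); (*Phiq)(row+2, bB+6+i) -= 0.5*b0(i);
      }
      // wrt femur columns f_a: dPhi0/df_a = (H(a,2) t1 - H(a,1) t2)/2, etc.
      for (int a=0;a<3;a++) for (int i=0;i<3;i++) {
        (*Phiq)(row+0, bA+3+3*a+i) += 0.5*(H(a,2)*t1(i) - H(a,1)*t2(i));
        (*Phiq)(row+1, bA+3+3*a+i) += 0.5*(H(a,0)*t2(i) - H(a,2)*t0(i));
        (*Phiq)(row+2, bA+3+3*a+i) += 0.5*(H(a,1)*t0(i) - H(a,0)*t1(i));
      }
      mat33 Bp = Rf*skew3(o.axis)*G*o.R0;
      vec3 dth = axial3(Bp.t()*Rt);
      for (int i=0;i<3;i++) (*Phiq)(row+i, o.idx) = dth(i);
    }
    row += 3;
  }

  for (size_t d=0; d<mod.drivers.size(); ++d) {
    int c = mod.drivers[d].coord;
    phi(row) = q(c) - dpos((uword)d);
    if (Phiq) (*Phiq)(row, c) = 1.0;
    row += 1;
  }
}

// Phi_t: partial time derivative (driver rows only)
static vec phit_vec(const Model &mod, const vec &dvel) {
  vec pt(mod.m, fill::zeros);
  int row = mod.m - (int)mod.drivers.size();
  for (size_t d=0; d<mod.drivers.size(); ++d) pt(row+(int)d) = -dvel((uword)d);
  return pt;
}

// Gamma = Phidot_q qdot + d(Phi_t)/dt : the acceleration-level constraint is
// Phiq qddot = -Gamma.
static vec gamma_vec(const Model &mod, const vec &q, const vec &qd, const vec &dacc) {
  vec g(mod.m, fill::zeros);
  int row = 0;
  for (int b : mod.rigid) {
    int base = bbase(b);
    vec3 du,dv,dw;
    for (int i=0;i<3;i++){ du(i)=qd(base+3+i); dv(i)=qd(base+6+i); dw(i)=qd(base+9+i); }
    g(row+0)=2*dot(du,du); g(row+1)=2*dot(dv,dv); g(row+2)=2*dot(dw,dw);
    g(row+3)=2*dot(du,dv); g(row+4)=2*dot(du,dw); g(row+5)=2*dot(dv,dw);
    row += 6;
  }
  row += 3*(int)mod.fixpts.size();   // linear in q: zero curvature
  row += 3*(int)mod.coinc.size();
  for (const OrientEuler &o : mod.oeuler) {
    double a1=q(o.idx(0)), a2=q(o.idx(1)), a3=q(o.idx(2));
    double w1=qd(o.idx(0)), w2=qd(o.idx(1)), w3=qd(o.idx(2));
    EulerB e = euler_zxy(a1,a2,a3,o.R0);
    static const vec3 ex={1,0,0}, ey={0,1,0}, ez={0,0,1};
    mat33 Sz=skew3(ez), Sx=skew3(ex), Sy=skew3(ey);
    mat33 Bdot = w1*e.d1 + w2*e.d2 + w3*e.d3;
    mat33 B2 = w1*w1*(Sz*e.d1) + w2*w2*(e.A1*Sx*Sx*e.A2*e.P3) + w3*w3*(e.A1*e.A2*Sy*Sy*e.P3)
             + 2*w1*w2*(Sz*e.A1*Sx*e.A2*e.P3) + 2*w1*w3*(Sz*e.A1*e.A2*Sy*e.P3)
             + 2*w2*w3*(e.A1*Sx*e.A2*Sy*e.P3);
    mat33 R = body_R(q, o.body);
    mat33 Rdot;
    int base=bbase(o.body);
    for (int j=0;j<3;j++) for (int i=0;i<3;i++) Rdot(i,j)=qd(base+3+3*j+i);
    vec3 gg = axial3(B2.t()*R + 2.0*(Bdot.t()*Rdot));
    for (int i=0;i<3;i++) g(row+i) = gg(i);
    row += 3;
  }
  for (const OrientRel &o : mod.orel) {
    double th=q(o.idx), w=qd(o.idx);
    mat33 G = rot_axis(o.axis, th);
    mat33 Sa = skew3(o.axis);
    mat33 Rf = body_R(q,o.bodyA), Rt = body_R(q,o.bodyB);
    int bA=bbase(o.bodyA), bB=bbase(o.bodyB);
    mat33 Rfd, Rtd;
    for (int j=0;j<3;j++) for (int i=0;i<3;i++) { Rfd(i,j)=qd(bA+3+3*j+i); Rtd(i,j)=qd(bB+3+3*j+i); }
    mat33 Bkdot = Rfd*G*o.R0 + w*(Rf*Sa*G*o.R0);
    mat33 B2 = 2.0*w*(Rfd*Sa*G*o.R0) + w*w*(Rf*Sa*Sa*G*o.R0);
    vec3 gg = axial3(B2.t()*Rt + 2.0*(Bkdot.t()*Rtd));
    for (int i=0;i<3;i++) g(row+i) = gg(i);
    row += 3;
  }
  for (size_t d=0; d<mod.drivers.size(); ++d) { g(row) = -dacc((uword)d); row += 1; }
  return g;
}

// ---------------------------------------------------------------------------
// forces (springs + contact), with approximate tangents for the Newton matrix
// ---------------------------------------------------------------------------

struct ContactMem {
  bool active = false;     // contact active at last accepted state
  bool allow = true;       // contact permitted (in domain, not blocked)
  bool blocked = false;    // dislocated/traversing: wait for separation
  bool has_ddot0 = false;
  double ddot0 = 0.0;
  double u = 0.0, v = 0.0; // closest-point seed
  bool seeded = false;
};

// a body passing behind the surface re-engages contact only on a fresh
// shallow approach; deeper "first contact" marks an unphysical traversal
static const double REENGAGE_DELTA = 2e-3;   // m

struct ContactOut {
  double delta=0, ddot=0, mag=0, u=0, v=0, dist=0;
  bool pen=false, in_dom=false, converged=true;
  vec3 point, normal;
};

// evaluate one contact pair at (q,qd); "allow" gates force generation
static void eval_contact(const Model &mod, const Contact &c, const vec &q, const vec &qd,
                         const ContactMem &mem, ContactOut &out) {
  vec3 s = point_pos(q, c.sphere_body, c.center);
  vec3 vs = point_vel(qd, c.sphere_body, c.center);
  mat33 Rs_g; vec3 os_g;
  if (c.surf_body < 0) { Rs_g = c.Rs; os_g = c.os; }
  else { mat33 Rb = body_R(q, c.surf_body); Rs_g = Rb*c.Rs; os_g = point_pos(q, c.surf_body, c.os); }
  vec3 cs = Rs_g.t()*(s - os_g);
  double u0 = mem.seeded ? mem.u : cs(0);
  double v0 = mem.seeded ? mem.v : cs(1);
  double u,v;
  out.converged = poly_closest(c.coef, cs, u0, v0, u, v);
  double z; poly_eval(c.coef, u, v, &z);
  vec3 ps = {u,v,z};
  double dist = norm(cs-ps);
  out.u=u; out.v=v; out.dist=dist;
  out.delta = c.radius - dist;
  out.in_dom = (u >= c.dom(0) && u <= c.dom(1) && v >= c.dom(2) && v <= c.dom(3));
  out.pen = out.delta > 0;
  vec3 n_s = (cs-ps); double nn = norm(n_s);
  if (nn < 1e-12) { n_s = {0,0,1}; nn = 1; }
  n_s /= nn;
  out.normal = Rs_g*n_s;
  out.point  = Rs_g*ps + os_g;
  // material velocity of the surface point
  vec3 vc(fill::zeros);
  vec3 b_loc(fill::zeros);
  if (c.surf_body >= 0) {
    mat33 Rb = body_R(q, c.surf_body);
    vec3 rb; for (int i=0;i<3;i++) rb(i)=q(bbase(c.surf_body)+i);
    b_loc = Rb.t()*(out.point - rb);
    vc = point_vel(qd, c.surf_body, b_loc);
  }
  out.ddot = -dot(out.normal, vs - vc);
  out.mag = 0.0;
  if (out.pen && mem.allow) {
    double ddot0_eff = mem.has_ddot0 ? mem.ddot0 : out.ddot;
    double factor = 1.0;
    if (std::fabs(ddot0_eff) >= EPS_DDOT0 && c.eps < 1.0)
      factor = 1.0 + (8.0*(1.0-c.eps))/(5.0*c.eps) * out.ddot/ddot0_eff;
    double mag = c.kn*std::pow(out.delta, c.p)*factor;
    out.mag = std::max(mag, 0.0);   // unilateral: no tensile contact
  }
}

// assemble generalized forces; optionally accumulate stiffness/damping tangents
static void assemble_forces(const Model &mod, const vec &q, const vec &qd,
                            const std::vector<ContactMem> &mem,
                            vec &Q, vec &tensions, std::vector<ContactOut> &couts,
                            mat *K=nullptr, mat *C=nullptr) {
  Q = mod.Qg;
  tensions.set_size(mod.springs.size());
  couts.resize(mod.contacts.size());

  for (size_t si=0; si<mod.springs.size(); ++si) {
    const Spring &s = mod.springs[si];
    vec3 pA = (s.bodyA>=0) ? point_pos(q,s.bodyA,s.localA) : s.localA;
    vec3 pB = (s.bodyB>=0) ? point_pos(q,s.bodyB,s.localB) : s.localB;
    vec3 vA = (s.bodyA>=0) ? point_vel(qd,s.bodyA,s.localA) : vec3(fill::zeros);
    vec3 vB = (s.bodyB>=0) ? point_vel(qd,s.bodyB,s.localB) : vec3(fill::zeros);
    vec3 d = pB-pA;
    double l = norm(d);
    if (l < 1e-9) Rcpp::stop("zero-length spring encountered");
    vec3 nrm = d/l;
    double ldot = dot(nrm, vB-vA);
    double T = s.k*(l - s.l0) + s.c*ldot;
    tensions((uword)si) = T;
    vec3 f = T*nrm;             // force on point A (pulled toward B)
    add_point_force(Q, s.bodyA, s.localA,  f);
    add_point_force(Q, s.bodyB, s.localB, -f);
    if (K) {
      mat33 Kd = s.k*(nrm*nrm.t());
      if (T != 0.0) Kd += (T/l)*(eye(3,3) - nrm*nrm.t());
      add_pair_block(*K, s.bodyA, s.localA, s.bodyA, s.localA, Kd,  1.0);
      add_pair_block(*K, s.bodyB, s.localB, s.bodyB, s.localB, Kd,  1.0);
      add_pair_block(*K, s.bodyA, s.localA, s.bodyB, s.localB, Kd, -1.0);
      add_pair_block(*K, s.bodyB, s.localB, s.bodyA, s.localA, Kd, -1.0);
    }
    if (C && s.c > 0) {
      mat33 Cd = s.c*(nrm*nrm.t());
      add_pair_block(*C, s.bodyA, s.localA, s.bodyA, s.localA, Cd,  1.0);
      add_pair_block(*C, s.bodyB, s.localB, s.bodyB, s.localB, Cd,  1.0);
      add_pair_block(*C, s.bodyA, s.localA, s.bodyB, s.localB, Cd, -1.0);
      add_pair_block(*C, s.bodyB, s.localB, s.bodyA, s.localA, Cd, -1.0);
    }
  }

  for (size_t ci=0; ci<mod.contacts.size(); ++ci) {
    const Contact &c = mod.contacts[ci];
    ContactOut &o = couts[ci];
    eval_contact(mod, c, q, qd, mem[ci], o);
    if (o.mag > 0) {
      vec3 F = o.mag*o.normal;
      add_point_force(Q, c.sphere_body, c.center, F);
      if (c.surf_body >= 0) {
        mat33 Rb = body_R(q, c.surf_body);
        vec3 rb; for (int i=0;i<3;i++) rb(i)=q(bbase(c.surf_body)+i);
        vec3 b_loc = Rb.t()*(o.point - rb);
        add_point_force(Q, c.surf_body, b_loc, -F);
      }
      if (K) {
        double ddot0_eff = mem[ci].has_ddot0 ? mem[ci].ddot0 : o.ddot;
        double factor = 1.0;
        if (std::fabs(ddot0_eff) >= EPS_DDOT0 && c.eps < 1.0)
          factor = 1.0 + (8.0*(1.0-c.eps))/(5.0*c.eps)*o.ddot/ddot0_eff;
        double dmag = c.kn*c.p*std::pow(std::max(o.delta,1e-12), c.p-1.0)*std::max(factor,0.0);
        mat33 Kd = dmag*(o.normal*o.normal.t());
        add_pair_block(*K, c.sphere_body, c.center, c.sphere_body, c.center, Kd, 1.0);
        if (C && std::fabs(ddot0_eff) >= EPS_DDOT0 && c.eps < 1.0) {
          double dmagv = c.kn*std::pow(o.delta, c.p)*(8.0*(1.0-c.eps))/(5.0*c.eps*ddot0_eff);
          if (dmagv > 0) {
            mat33 Cd = dmagv*(o.normal*o.normal.t());
            add_pair_block(*C, c.sphere_body, c.center, c.sphere_body, c.center, Cd, 1.0);
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// exported single-shot assembly (R-level assemble_system and tests)
// ---------------------------------------------------------------------------

static std::vector<ContactMem> fresh_memory(const Model &mod) {
  return std::vector<ContactMem>(mod.contacts.size());
}

static Rcpp::List contact_list(const std::vector<ContactOut> &couts) {
  Rcpp::List cl(couts.size());
  for (size_t i=0;i<couts.size();++i) {
    const ContactOut &o = couts[i];
    cl[i] = Rcpp::List::create(
      Rcpp::Named("delta")=o.delta, Rcpp::Named("ddot")=o.ddot,
      Rcpp::Named("force")=o.mag, Rcpp::Named("penetrating")=o.pen,
      Rcpp::Named("in_domain")=o.in_dom,
      Rcpp::Named("u")=o.u, Rcpp::Named("v")=o.v, Rcpp::Named("distance")=o.dist,
      Rcpp::Named("point")=Rcpp::NumericVector::create(o.point(0),o.point(1),o.point(2)),
      Rcpp::Named("normal")=Rcpp::NumericVector::create(o.normal(0),o.normal(1),o.normal(2)));
  }
  return cl;
}

// [[Rcpp::export(name = ".cpp_assemble")]]
Rcpp::List cpp_assemble(const Rcpp::List &model, const arma::vec &q,
                        const arma::vec &qdot, const arma::vec &driver_pos) {
  Model mod = parse_model(model);
  vec phi; mat Phiq;
  assemble_phi(mod, q, driver_pos, phi, &Phiq);
  vec Q, tensions; std::vector<ContactOut> couts;
  std::vector<ContactMem> mem = fresh_memory(mod);
  assemble_forces(mod, q, qdot, mem, Q, tensions, couts);
  if (!Q.is_finite() || !phi.is_finite())
    Rcpp::stop("non-finite entries in assembled system (corrupted state?)");
  return Rcpp::List::create(
    Rcpp::Named("M")=mod.M, Rcpp::Named("Q")=Q,
    Rcpp::Named("phi")=phi, Rcpp::Named("phiq")=Phiq,
    Rcpp::Named("tensions")=tensions,
    Rcpp::Named("contacts")=contact_list(couts));
}

// [[Rcpp::export(name = ".cpp_constraints")]]
Rcpp::List cpp_constraints(const Rcpp::List &model, const arma::vec &q,
                           const arma::vec &qdot, const arma::vec &driver_pos,
                           const arma::vec &driver_vel, const arma::vec &driver_acc) {
  Model mod = parse_model(model);
  vec phi; mat Phiq;
  assemble_phi(mod, q, driver_pos, phi, &Phiq);
  vec pt = phit_vec(mod, driver_vel);
  vec gm = gamma_vec(mod, q, qdot, driver_acc);
  return Rcpp::List::create(Rcpp::Named("phi")=phi, Rcpp::Named("phiq")=Phiq,
                            Rcpp::Named("phit")=pt, Rcpp::Named("gamma")=gm);
}

// [[Rcpp::export(name = ".cpp_contact_eval")]]
Rcpp::List cpp_contact_eval(const Rcpp::List &model, const arma::vec &q,
                            const arma::vec &qdot) {
  Model mod = parse_model(model);
  std::vector<ContactMem> mem = fresh_memory(mod);
  std::vector<ContactOut> couts(mod.contacts.size());
  for (size_t i=0;i<mod.contacts.size();++i)
    eval_contact(mod, mod.contacts[i], q, qdot, mem[i], couts[i]);
  return contact_list(couts);
}

// ---------------------------------------------------------------------------
// projections: mass-weighted KKT solves at position q
// ---------------------------------------------------------------------------

static void project_state(const Model &mod, const vec &q,
                          const vec &dpos, const vec &dvel, const vec &dacc,
                          vec &qd, vec &qdd, double *velnorm=nullptr, double *accnorm=nullptr) {
  vec phi; mat Phiq;
  assemble_phi(mod, q, dpos, phi, &Phiq);
  int n = mod.n, m = mod.m;
  mat KKT(n+m, n+m, fill::zeros);
  KKT.submat(0,0,n-1,n-1) = mod.M;
  KKT.submat(0,n,n-1,n+m-1) = Phiq.t();
  KKT.submat(n,0,n+m-1,n-1) = Phiq;
  vec pt = phit_vec(mod, dvel);
  vec rhs_v(n+m, fill::zeros);
  rhs_v.subvec(0,n-1) = mod.M*qd;
  rhs_v.subvec(n,n+m-1) = -pt;
  vec sol_v = solve(KKT, rhs_v);
  qd = sol_v.subvec(0,n-1);
  vec gm = gamma_vec(mod, q, qd, dacc);
  vec rhs_a(n+m, fill::zeros);
  rhs_a.subvec(0,n-1) = mod.M*qdd;
  rhs_a.subvec(n,n+m-1) = -gm;
  vec sol_a = solve(KKT, rhs_a);
  qdd = sol_a.subvec(0,n-1);
  if (velnorm) *velnorm = norm(Phiq*qd + pt, "inf");
  if (accnorm) *accnorm = norm(Phiq*qdd + gm, "inf");
}

// [[Rcpp::export(name = ".cpp_project")]]
Rcpp::List cpp_project(const Rcpp::List &model, const arma::vec &q,
                       const arma::vec &qdot, const arma::vec &qddot,
                       const arma::vec &driver_pos, const arma::vec &driver_vel,
                       const arma::vec &driver_acc) {
  Model mod = parse_model(model);
  vec qd = qdot, qdd = qddot;
  double vn, an;
  project_state(mod, q, driver_pos, driver_vel, driver_acc, qd, qdd, &vn, &an);
  return Rcpp::List::create(Rcpp::Named("qdot")=qd, Rcpp::Named("qddot")=qdd,
                            Rcpp::Named("vel_norm")=vn, Rcpp::Named("acc_norm")=an);
}

// ---------------------------------------------------------------------------
// static equilibrium: damped Gauss-Newton on the residual of the equilibrium
// equations (accelerations and velocity-dependent forces removed), with
// nested approximate-multiplier updates.
// ---------------------------------------------------------------------------

// project each body's rotation columns back onto SO(3) (polar decomposition);
// keeps finite rotation steps from violating the quadratic rigid-body
// constraints at second order (which the penalty would otherwise punish)
static void orthonormalize_bodies(const Model &mod, vec &q) {
  for (int b = 0; b < mod.n_bodies; ++b) {
    mat33 R = body_R(q, b);
    mat U, V; vec s;
    if (!svd(U, s, V, R)) continue;
    mat33 Rn = U*V.t();
    if (det(Rn) < 0) { U.col(2) *= -1.0; Rn = U*V.t(); }
    int base = bbase(b);
    for (int j=0;j<3;j++) for (int i=0;i<3;i++) q(base+3+3*j+i) = Rn(i,j);
  }
}

static vec static_residual(const Model &mod, const vec &q, const vec &lambda,
                           const vec &dpos, const std::vector<ContactMem> &mem,
                           vec *phi_out=nullptr) {
  vec phi; mat Phiq;
  assemble_phi(mod, q, dpos, phi, &Phiq);
  vec Q, tensions; std::vector<ContactOut> couts;
  vec qd(mod.n, fill::zeros);
  assemble_forces(mod, q, qd, mem, Q, tensions, couts);
  if (phi_out) *phi_out = phi;
  return Phiq.t()*(lambda + mod.alpha*phi) - Q;
}

// [[Rcpp::export(name = ".cpp_static_equilibrium")]]
Rcpp::List cpp_static_equilibrium(const Rcpp::List &model, const arma::vec &q_guess,
                                  const arma::vec &driver_pos,
                                  double tol, double phi_tol, int maxit) {
  Model mod = parse_model(model);
  vec q = q_guess;
  std::vector<ContactMem> mem = fresh_memory(mod);
  int n = mod.n, m = mod.m;
  // Newton-Raphson on the extended static system
  //   Phiq^T lambda = Q(q, 0),  Phi(q) = 0
  // (accelerations and velocity-dependent forces removed). Multipliers are
  // recovered by least squares at each iterate; trial steps re-orthonormalize
  // the body rotations. A small regularization handles the nearly neutral
  // patella spin direction.
  auto eval_at = [&](const vec &qq, vec &phi, mat &Phiq, vec &Q, vec &lam, vec &rstat) {
    assemble_phi(mod, qq, driver_pos, phi, &Phiq);
    vec tensions; std::vector<ContactOut> couts;
    vec qd(n, fill::zeros);
    assemble_forces(mod, qq, qd, mem, Q, tensions, couts);
    mat G = Phiq*Phiq.t();
    lam = solve(G + 1e-12*trace(G)/m*eye(m,m), Phiq*Q);
    rstat = Phiq.t()*lam - Q;
  };
  auto merit = [&](const vec &qq) {
    vec phi, Q, lam, rstat; mat Phiq;
    eval_at(qq, phi, Phiq, Q, lam, rstat);
    return norm(rstat) + 1e3*norm(phi);
  };
  vec phi, Q, lam, rstat; mat Phiq;
  double step_inf = datum::inf, phi_inf = datum::inf, res_inf = datum::inf;
  bool ok = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    eval_at(q, phi, Phiq, Q, lam, rstat);
    res_inf = norm(rstat, "inf");
    phi_inf = norm(phi, "inf");
    if (res_inf < 1e-8 && phi_inf < phi_tol) { ok = true; break; }
    if (step_inf < 1e-14) break;   // stalled
    // finite-difference Jacobian of q -> Phiq^T lam - Q at fixed multipliers
    // (penalty-free residual: the saddle system stays well scaled)
    auto resid_np = [&](const vec &qq) {
      vec ph; mat Pq;
      assemble_phi(mod, qq, driver_pos, ph, &Pq);
      vec QQ, tens; std::vector<ContactOut> co;
      vec qd(n, fill::zeros);
      assemble_forces(mod, qq, qd, mem, QQ, tens, co);
      return vec(Pq.t()*lam - QQ);
    };
    mat J(n, n);
    double h = 1e-6;
    for (int j=0; j<n; ++j) {
      vec qp = q, qm = q;
      qp(j) += h; qm(j) -= h;
      J.col(j) = (resid_np(qp) - resid_np(qm))/(2*h);
    }
    mat KKT(n+m, n+m, fill::zeros);
    KKT.submat(0,0,n-1,n-1) = J + 1e-6*eye(n,n);
    KKT.submat(0,n,n-1,n+m-1) = Phiq.t();
    KKT.submat(n,0,n+m-1,n-1) = Phiq;
    vec rhs(n+m, fill::zeros);
    rhs.subvec(0,n-1) = -rstat;
    rhs.subvec(n,n+m-1) = -phi;
    vec sol;
    if (!solve(sol, KKT, rhs, solve_opts::no_approx) || !sol.is_finite()) break;
    vec dq = sol.subvec(0,n-1);
    double sn = norm(dq, "inf");
    if (sn > 0.1) dq *= 0.1/sn;
    double m0 = norm(rstat) + 1e3*norm(phi);
    double t = 1.0;
    vec q_best = q; double m_best = m0; bool improved = false;
    for (int ls = 0; ls < 9; ++ls) {
      vec q_try = q + t*dq;
      orthonormalize_bodies(mod, q_try);
      double mt = merit(q_try);
      if (mt < m_best) { m_best = mt; q_best = q_try; improved = true; break; }
      t *= 0.5;
    }
    if (!improved) break;
    step_inf = t*norm(dq, "inf");
    q = q_best;
  }
  vec lambda = lam;   // reported multipliers (penalty term vanishes as Phi -> 0)
  vec phi_final;
  assemble_phi(mod, q, driver_pos, phi_final, nullptr);
  return Rcpp::List::create(
    Rcpp::Named("q")=q, Rcpp::Named("lambda")=lambda,
    Rcpp::Named("converged")=ok, Rcpp::Named("iterations")=it,
    Rcpp::Named("residual_norm")=res_inf,
    Rcpp::Named("phi_norm")=norm(phi_final,"inf"));
}

// ---------------------------------------------------------------------------
// Newmark / ALI3-P time stepping
// ---------------------------------------------------------------------------

struct Settings {
  double h, gamma, beta, deltaf, deltam, newton_tol, phi_tol, vel_scale;
  int maxit, record_every;
};

static Settings parse_settings(const Rcpp::List &s) {
  Settings st;
  st.h = Rcpp::as<double>(s["step_h"]);
  st.gamma = Rcpp::as<double>(s["newmark_gamma"]);
  st.beta = Rcpp::as<double>(s["newmark_beta"]);
  st.deltaf = Rcpp::as<double>(s["delta_f"]);
  st.deltam = Rcpp::as<double>(s["delta_m"]);
  st.newton_tol = Rcpp::as<double>(s["newton_tol"]);
  st.phi_tol = Rcpp::as<double>(s["projection_tol"]);
  st.maxit = Rcpp::as<int>(s["max_newton_iters"]);
  st.record_every = Rcpp::as<int>(s["record_every"]);
  st.vel_scale = s.containsElementNamed("vel_scale") ?
    Rcpp::as<double>(s["vel_scale"]) : 1.0;
  return st;
}

// One accepted step; updates q, qd, qdd, lambda and the contact memory.
// Returns Newton iteration count, or -1 on failure.
static int newmark_step_core(const Model &mod, const Settings &st,
                             vec &q, vec &qd, vec &qdd, vec &lambda,
                             std::vector<ContactMem> &mem,
                             const vec &dpos, const vec &dvel, const vec &dacc,
                             double *phi_out, double *res_out) {
  const double h = st.h, bet = st.beta, gam = st.gamma;
  vec q_n = q, qd_n = qd, qdd_n = qdd;
  // constant-acceleration predictor
  vec qc = q_n + h*qd_n + 0.5*h*h*qdd_n;
  int n = mod.n;
  vec phi; mat Phiq;
  vec Q, tensions; std::vector<ContactOut> couts;
  mat K(n,n), C(n,n);
  int it; double step_inf = datum::inf, phi_inf = datum::inf;
  double last_res = datum::inf;
  for (it = 0; it < st.maxit; ++it) {
    vec qd_c  = (gam/(bet*h))*(qc - q_n) + qd_n*(1.0 - gam/bet) + h*qdd_n*(1.0 - gam/(2.0*bet));
    vec qdd_c = (qc - q_n)/(bet*h*h) - qd_n/(bet*h) - qdd_n*(1.0/(2.0*bet) - 1.0);
    assemble_phi(mod, qc, dpos, phi, &Phiq);
    lambda += mod.alpha*phi;                       // multiplier update
    K.zeros(); C.zeros();
    assemble_forces(mod, qc, qd_c, mem, Q, tensions, couts, &K, &C);
    vec g = st.deltam*(mod.M*qdd_c) + st.deltaf*(Phiq.t()*(lambda + mod.alpha*phi) - Q);
    last_res = norm(g, "inf");
    phi_inf = norm(phi, "inf");
    if (it > 0 && step_inf < st.newton_tol && phi_inf < st.phi_tol) break;
    mat T = (st.deltam/(bet*h*h))*mod.M
          + st.deltaf*(mod.alpha*(Phiq.t()*Phiq) + K + (gam/(bet*h))*C);
    vec dq;
    bool solved = solve(dq, T, -g, solve_opts::no_approx);
    if (!solved || !dq.is_finite()) return -1;
    qc += dq;
    step_inf = norm(dq, "inf");
  }
  if (!(phi_inf < st.phi_tol)) return -1;
  // accepted: recover velocities/accelerations and project
  vec qd_c  = (gam/(bet*h))*(qc - q_n) + qd_n*(1.0 - gam/bet) + h*qdd_n*(1.0 - gam/(2.0*bet));
  vec qdd_c = (qc - q_n)/(bet*h*h) - qd_n/(bet*h) - qdd_n*(1.0/(2.0*bet) - 1.0);
  project_state(mod, qc, dpos, dvel, dacc, qd_c, qdd_c);
  q = qc; qd = qd_c; qdd = qdd_c;
  if (phi_out) *phi_out = phi_inf;
  if (res_out) *res_out = last_res;
  return it;
}

// update contact episode memory at an accepted state; returns dislocation flags
static void update_memory(const Model &mod, const vec &q, const vec &qd,
                          std::vector<ContactMem> &mem,
                          std::vector<int> &dislocated, std::vector<ContactOut> &outs) {
  outs.resize(mod.contacts.size());
  dislocated.assign(mod.contacts.size(), 0);
  for (size_t i=0;i<mod.contacts.size();++i) {
    ContactOut o;
    eval_contact(mod, mod.contacts[i], q, qd, mem[i], o);
    outs[i] = o;
    ContactMem &m = mem[i];
    if (!o.converged) {                      // closest point unreliable: stand down
      m.active = false; m.allow = false; m.seeded = false;
      m.has_ddot0 = false; m.ddot0 = 0.0;
      continue;
    }
    if (m.active && o.pen && !o.in_dom) {    // left the fitted surface patch
      dislocated[i] = 1;
      m.blocked = true;
    }
    if (o.pen && !m.active && !m.blocked && o.delta >= REENGAGE_DELTA)
      m.blocked = true;                      // traversal from behind
    if (!o.pen) m.blocked = false;           // separated: normal behavior resumes
    bool now_active = o.pen && o.in_dom && !m.blocked;
    if (now_active && !m.active) {           // episode onset: latch ddot0
      m.has_ddot0 = std::fabs(o.ddot) >= EPS_DDOT0;
      m.ddot0 = o.ddot;
    }
    if (!o.pen) { m.has_ddot0 = false; m.ddot0 = 0.0; }
    m.active = now_active;
    m.allow = o.in_dom && !m.blocked;
    m.u = o.u; m.v = o.v; m.seeded = true;
  }
}

// [[Rcpp::export(name = ".cpp_simulate")]]
Rcpp::List cpp_simulate(const Rcpp::List &model, const Rcpp::List &settings,
                        const arma::vec &q0, const arma::vec &qd0,
                        const arma::vec &lambda0,
                        const arma::mat &driver_pos, const arma::mat &driver_vel,
                        const arma::mat &driver_acc, double t0) {
  Model mod = parse_model(model);
  Settings st = parse_settings(settings);
  int nsteps = (int)driver_pos.n_rows - 1;
  int nd = (int)mod.drivers.size();
  if ((int)driver_pos.n_cols != nd) Rcpp::stop("driver array has wrong number of columns");

  vec q = q0;
  vec lambda = (lambda0.n_elem == (uword)mod.m) ? lambda0 : vec(mod.m, fill::zeros);
  std::vector<ContactMem> mem = fresh_memory(mod);

  // consistent initial velocity / acceleration via the projection solves
  vec qd(mod.n, fill::zeros), qdd(mod.n, fill::zeros);
  {
    std::vector<int> disl; std::vector<ContactOut> outs;
    update_memory(mod, q, qd, mem, disl, outs);
    // initial episode: contact present at t0 starts as a (quasi-)static episode
    vec phi; mat Phiq;
    assemble_phi(mod, q, driver_pos.row(0).t(), phi, &Phiq);
    vec Q, tensions; std::vector<ContactOut> couts;
    assemble_forces(mod, q, qd, mem, Q, tensions, couts);
    int n = mod.n, m = mod.m;
    mat KKT(n+m,n+m,fill::zeros);
    KKT.submat(0,0,n-1,n-1)=mod.M;
    KKT.submat(0,n,n-1,n+m-1)=Phiq.t();
    KKT.submat(n,0,n+m-1,n-1)=Phiq;
    vec pt = phit_vec(mod, driver_vel.row(0).t());
    vec rhs(n+m,fill::zeros);
    if (qd0.n_elem == (uword)n) rhs.subvec(0,n-1) = mod.M*qd0;
    rhs.subvec(n,n+m-1) = -pt;
    vec sol = solve(KKT, rhs); qd = sol.subvec(0,n-1);
    vec gm = gamma_vec(mod, q, qd, driver_acc.row(0).t());
    vec rhs2(n+m,fill::zeros); rhs2.subvec(0,n-1)=Q - Phiq.t()*lambda;
    rhs2.subvec(n,n+m-1) = -gm;
    vec sol2 = solve(KKT, rhs2); qdd = sol2.subvec(0,n-1);
  }

  int rec_every = st.record_every;
  int nrec = nsteps/rec_every + 1;
  int nsp = (int)mod.springs.size(), nct = (int)mod.contacts.size();
  mat Qrec(nrec, mod.n), QDrec(nrec, mod.n), QDDrec(nrec, mod.n);
  vec trec(nrec), phirec(nrec), velrec(nrec), accrec(nrec);
  ivec itrec(nrec);
  mat tens_rec(nrec, std::max(nsp,1), fill::zeros);
  mat cf_rec(nrec, std::max(nct,1), fill::zeros);
  mat cd_rec(nrec, std::max(nct,1), fill::zeros);
  imat ca_rec(nrec, std::max(nct,1), fill::zeros);
  mat cu_rec(nrec, std::max(nct,1), fill::zeros);
  mat cv_rec(nrec, std::max(nct,1), fill::zeros);
  std::vector<double> ev_time; std::vector<int> ev_contact;

  bool failed = false; int fail_step = -1;

  // record initial state
  auto record = [&](int slot, double t, double phi_inf, int iters,
                    const std::vector<ContactOut> &outs, const vec &tensions,
                    double vn, double an) {
    Qrec.row(slot) = q.t(); QDrec.row(slot) = qd.t(); QDDrec.row(slot) = qdd.t();
    trec(slot)=t; phirec(slot)=phi_inf; itrec(slot)=iters;
    velrec(slot)=vn; accrec(slot)=an;
    for (int s=0;s<nsp;s++) tens_rec(slot,s)=tensions((uword)s);
    for (int c=0;c<nct;c++) {
      cf_rec(slot,c)=outs[(size_t)c].mag;
      cd_rec(slot,c)=outs[(size_t)c].delta;
      ca_rec(slot,c)=(outs[(size_t)c].mag>0)?1:0;
      cu_rec(slot,c)=outs[(size_t)c].u;
      cv_rec(slot,c)=outs[(size_t)c].v;
    }
  };

  {
    vec phi; assemble_phi(mod, q, driver_pos.row(0).t(), phi, nullptr);
    vec Q, tensions; std::vector<ContactOut> couts;
    assemble_forces(mod, q, qd, mem, Q, tensions, couts);
    record(0, t0, norm(phi,"inf"), 0, couts, tensions, 0.0, 0.0);
  }

  int slot = 1;
  for (int stp = 1; stp <= nsteps; ++stp) {
    double t = t0 + st.h*stp;
    double phi_inf=0, res=0;
    int iters = newmark_step_core(mod, st, q, qd, qdd, lambda, mem,
                                  driver_pos.row(stp).t(), driver_vel.row(stp).t(),
                                  driver_acc.row(stp).t(), &phi_inf, &res);
    if (iters < 0) { failed = true; fail_step = stp; break; }
    std::vector<int> disl; std::vector<ContactOut> outs;
    update_memory(mod, q, qd, mem, disl, outs);
    for (int c=0;c<nct;c++) if (disl[(size_t)c]) { ev_time.push_back(t); ev_contact.push_back(c+1); }
    if (st.vel_scale != 1.0) { qd *= st.vel_scale; qdd *= st.vel_scale; }
    if (stp % rec_every == 0) {
      vec Q, tensions; std::vector<ContactOut> couts;
      assemble_forces(mod, q, qd, mem, Q, tensions, couts);
      // velocity/acceleration constraint norms at the accepted state
      vec phi; mat Phiq;
      assemble_phi(mod, q, driver_pos.row(stp).t(), phi, &Phiq);
      vec pt = phit_vec(mod, driver_vel.row(stp).t());
      vec gm = gamma_vec(mod, q, qd, driver_acc.row(stp).t());
      double vn = norm(Phiq*qd + pt, "inf");
      double an = norm(Phiq*qdd + gm, "inf");
      record(slot, t, phi_inf, iters, outs, tensions, vn, an);
      slot++;
    }
  }

  int used = failed ? slot : nrec;
  Rcpp::NumericMatrix events(ev_time.size(), 2);
  for (size_t i=0;i<ev_time.size();++i) { events(i,0)=ev_time[i]; events(i,1)=ev_contact[i]; }

  return Rcpp::List::create(
    Rcpp::Named("t")=trec.subvec(0,used-1),
    Rcpp::Named("q")=Qrec.rows(0,used-1),
    Rcpp::Named("qdot")=QDrec.rows(0,used-1),
    Rcpp::Named("qddot")=QDDrec.rows(0,used-1),
    Rcpp::Named("phi_norm")=phirec.subvec(0,used-1),
    Rcpp::Named("vel_norm")=velrec.subvec(0,used-1),
    Rcpp::Named("acc_norm")=accrec.subvec(0,used-1),
    Rcpp::Named("newton_iters")=itrec.subvec(0,used-1),
    Rcpp::Named("tensions")=tens_rec.rows(0,used-1),
    Rcpp::Named("contact_force")=cf_rec.rows(0,used-1),
    Rcpp::Named("contact_delta")=cd_rec.rows(0,used-1),
    Rcpp::Named("contact_active")=ca_rec.rows(0,used-1),
    Rcpp::Named("contact_u")=cu_rec.rows(0,used-1),
    Rcpp::Named("contact_v")=cv_rec.rows(0,used-1),
    Rcpp::Named("events")=events,
    Rcpp::Named("failed")=failed,
    Rcpp::Named("fail_step")=fail_step);
}

// [[Rcpp::export(name = ".cpp_newmark_step")]]
Rcpp::List cpp_newmark_step(const Rcpp::List &model, const Rcpp::List &settings,
                            const arma::vec &q, const arma::vec &qdot,
                            const arma::vec &qddot, const arma::vec &lambda,
                            const arma::vec &driver_pos, const arma::vec &driver_vel,
                            const arma::vec &driver_acc, bool project) {
  Model mod = parse_model(model);
  Settings st = parse_settings(settings);
  vec qq=q, qd=qdot, qdd=qddot, lam=lambda;
  std::vector<ContactMem> mem = fresh_memory(mod);
  {  // seed memory from the current state so episodes behave as mid-run
    std::vector<int> disl; std::vector<ContactOut> outs;
    update_memory(mod, qq, qd, mem, disl, outs);
  }
  double phi_inf=0, res=0;
  // without projection: run the raw Newton loop by temporarily projecting into
  // a copy (project_state is always executed inside the core; emulate by
  // saving the unprojected Newmark recovery)
  const double h=st.h, bet=st.beta, gam=st.gamma;
  vec q_n=qq, qd_n=qd, qdd_n=qdd;
  int iters = newmark_step_core(mod, st, qq, qd, qdd, lam, mem,
                                driver_pos, driver_vel, driver_acc, &phi_inf, &res);
  if (iters < 0) Rcpp::stop("Newton iteration failed to converge (last residual %g)", res);
  if (!project) {
    qd  = (gam/(bet*h))*(qq - q_n) + qd_n*(1.0 - gam/bet) + h*qdd_n*(1.0 - gam/(2.0*bet));
    qdd = (qq - q_n)/(bet*h*h) - qd_n/(bet*h) - qdd_n*(1.0/(2.0*bet) - 1.0);
  }
  return Rcpp::List::create(
    Rcpp::Named("q")=qq, Rcpp::Named("qdot")=qd, Rcpp::Named("qddot")=qdd,
    Rcpp::Named("lambda")=lam, Rcpp::Named("iters")=iters,
    Rcpp::Named("phi_norm")=phi_inf, Rcpp::Named("residual")=res);
}
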